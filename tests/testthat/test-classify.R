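# helpers to fabricate pairwise test results with a known structure
fake_test <- function(gene_id, fc, adj, A, B) {
  df <- data.frame(gene_id = gene_id, log2_fold_change = fc,
                   p_value = adj, adj_p = adj, stringsAsFactors = FALSE)
  attr(df, "groupA") <- A
  attr(df, "groupB") <- B
  df
}

# three morph comparisons for a single gene; fc_* oriented B-to-A
morph_tests <- function(fc_m_vs_p, adj_m_vs_p, fc_f_vs_p, adj_f_vs_p,
                        fc_f_vs_m, adj_f_vs_m) {
  list(
    fake_test("g1", fc_m_vs_p, adj_m_vs_p, "parthenogenetic_female", "male"),
    fake_test("g1", fc_f_vs_p, adj_f_vs_p, "parthenogenetic_female",
              "sexual_female"),
    fake_test("g1", fc_f_vs_m, adj_f_vs_m, "male", "sexual_female")
  )
}

test_that("the dual-comparison rule assigns morph bias and degree", {
  # overexpressed by males vs both others: adj 0.01, |fc| 1.5 -> male (+)
  tab <- classify_morph_bias(morph_tests(1.5, 0.01, 0.2, 0.9, -1.5, 0.01))
  expect_equal(tab$morph_bias, "male")
  expect_equal(tab$class, "M")
  expect_equal(tab$degree, "+")
  # fc 2.5 and 2.1 in the two male comparisons -> male-limited (++)
  tab <- classify_morph_bias(morph_tests(2.5, 0.001, 0.1, 0.8, -2.1, 0.001))
  expect_equal(tab$degree, "++")
  # significant against only one of the two others -> unbiased
  tab <- classify_morph_bias(morph_tests(1.5, 0.01, 0.0, 1.0, -0.2, 0.9))
  expect_equal(tab$morph_bias, "unbiased")
  expect_equal(tab$degree, "none")
})

test_that("threshold ties are strict: p = alpha or |fc| = 1 do not qualify", {
  tab <- classify_morph_bias(morph_tests(1.5, 0.05, 0.1, 0.9, -1.5, 0.05))
  expect_equal(tab$morph_bias, "unbiased")
  tab <- classify_morph_bias(morph_tests(1.0, 0.01, 0.1, 0.9, -1.0, 0.01))
  expect_equal(tab$morph_bias, "unbiased")
})

test_that("class labels are mutually exclusive and exhaustive", {
  set.seed(4)
  n <- 300
  mk <- function(A, B) fake_test(sprintf("g%03d", 1:n),
                                 rnorm(n, 0, 2), runif(n), A, B)
  tests <- list(mk("parthenogenetic_female", "male"),
                mk("parthenogenetic_female", "sexual_female"),
                mk("male", "sexual_female"))
  tab <- classify_morph_bias(tests)
  expect_true(all(tab$morph_bias %in% c("male", "sexual_female",
                                        "parthenogenetic_female", "unbiased")))
  expect_equal(tab$degree == "none", tab$morph_bias == "unbiased")
  expect_error(classify_morph_bias(tests[1:2]), "comparison")
})

test_that("tissue bias uses the same dual rule within a morph", {
  mk <- function(fc1, p1, fc2, p2, fc3, p3) list(
    fake_test("g1", fc1, p1, "head", "gonads"),
    fake_test("g1", fc2, p2, "legs", "gonads"),
    fake_test("g1", fc3, p3, "head", "legs"))
  tab <- classify_tissue_bias(list(male = mk(2, 0.01, 2.2, 0.01, 0, 1)))
  expect_equal(tab$tissue_bias_male, "gonads")
  # overexpressed versus head only -> none
  tab <- classify_tissue_bias(list(male = mk(2, 0.01, 0.1, 0.9, 0, 1)))
  expect_equal(tab$tissue_bias_male, "none")
  # flat gene -> none
  tab <- classify_tissue_bias(list(male = mk(0, 1, 0, 1, 0, 1)))
  expect_equal(tab$tissue_bias_male, "none")
})

test_that("chromosome annotation labels X, autosome and unplaced", {
  ann <- data.frame(gene_id = c("g1", "g2"), chromosome = c("X", "A1"))
  expect_equal(annotate_chromosome(c("g1", "g2"), ann), c("X", "autosome"))
  expect_warning(cls <- annotate_chromosome(c("g1", "gX"), ann), "unplaced")
  expect_equal(cls, c("X", "unplaced"))
})

test_that("classification on simulated outgroup data recovers truth labels", {
  cfg <- quick_cfg(13, n_genes = 1200, lfc_bias = 2)
  og <- simulate_outgroup(cfg)
  ct <- classify_outgroup(og$body, tissue = NULL)
  tb <- merge(ct, og$truth[, c("gene_id", "class", "baseline_log2")],
              by = "gene_id", suffixes = c("", ".true"))
  expect_gt(mean(tb$class == tb$class.true), 0.9)
  hi <- tb$class.true != "unbiased" & tb$baseline_log2 > 4
  expect_gt(mean(tb$class[hi] == tb$class.true[hi]), 0.85)
})
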
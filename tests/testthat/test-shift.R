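test_that("the OP-to-CP ratio follows its defining arithmetic", {
  p <- shift_params(pseudocount = 0.05)
  r <- op_cp_ratio(c(g1 = 1.0), c(g1 = 0.475), "male", p)
  expect_equal(r$ratio, 1.0, tolerance = 1e-12)  # log2(1.05/0.525)
  r <- op_cp_ratio(c(g1 = 1.0), c(g1 = 0), "male", p)
  expect_equal(r$ratio, log2(21), tolerance = 1e-12)  # ~4.392
  r <- op_cp_ratio(c(g1 = 3.3), c(g1 = 3.3), "male", p)
  expect_equal(r$ratio, 0)
  expect_error(op_cp_ratio(c(a = 1), c(b = 1), "male", p), "gene sets")
})

test_that("the ratio is antisymmetric and shrinks as the pseudocount grows", {
  set.seed(5)
  op <- setNames(rlnorm(50, 2, 1), sprintf("g%02d", 1:50))
  cp <- setNames(rlnorm(50, 2, 1), names(op))
  r1 <- op_cp_ratio(op, cp, "male")$ratio
  r2 <- op_cp_ratio(cp, op, "male")$ratio
  expect_equal(r1, -r2)
  big <- op_cp_ratio(op, cp, "male", shift_params(pseudocount = 1e6))$ratio
  expect_true(all(abs(big) <= abs(r1) + 1e-12))
  expect_lt(max(abs(big)), 1e-3)
})

test_that("the signed-rank class test matches sign-flip enumeration and limits", {
  # {1,2,3,4,5}: all positive, exact p = 2/32
  res <- wilcoxon_class_test(c(1, 2, 3, 4, 5))
  expect_equal(res$p_value, oracle_signrank_p(c(1, 2, 3, 4, 5)))
  expect_equal(res$p_value, 0.0625)
  expect_equal(res$median, 3)
  # symmetric ratios: p in the null acceptance region
  res <- wilcoxon_class_test(c(-3, -2, -1, 1, 2, 3))
  expect_gt(res$p_value, 0.9)
  # all-positive large sample with median ~0.13: overwhelming evidence
  set.seed(6)
  res <- wilcoxon_class_test(abs(rnorm(300, 0.13, 0.02)))
  expect_lt(res$p_value, 1e-10)
  expect_error(wilcoxon_class_test(numeric(0), "F"), "F")
})

test_that("subdivision panels restrict to genes carrying the key", {
  sh <- data.frame(
    gene_id = sprintf("g%d", 1:8),
    ratio = c(0.5, 0.4, 0.3, 0.2, -0.1, 0.1, 0.25, 0.15),
    class = c("F", "F", "F", "F", "unbiased", "unbiased", "M", "M"),
    degree = c("+", "+", "+", "+", "none", "none", "+", "+"),
    chromosome_class = c("X", "X", "autosome", "autosome", "X", "autosome",
                         "X", "autosome"),
    tissue_bias = c("gonads", "none", "gonads", "none", "none", "none",
                    "none", "none"))
  deg <- subdivide_and_test(sh, "degree")
  expect_true(all(deg$level == "+"))  # no ++ genes: only + reported
  expect_false("unbiased" %in% deg$class)
  tis <- subdivide_and_test(sh, "tissue_bias")
  expect_equal(unique(tis$level), "gonads")
  expect_equal(tis$n_genes[tis$class == "F"], 2)
  chr <- subdivide_and_test(sh, "chromosome_class")
  expect_setequal(unique(chr$level), c("autosome", "X"))
})

test_that("identical lineages give zero pairwise medians", {
  lm <- matrix(5, 4, 4, dimnames = list(
    sprintf("g%d", 1:4),
    c("CP1.male", "CP2.male", "OP1.male", "OP2.male")))
  ct <- data.frame(gene_id = sprintf("g%d", 1:4),
                   class = c("M", "F", "P", "unbiased"))
  pw <- pairwise_lineage_ratios(lm, "male", ct)
  expect_equal(nrow(pw), 2 * 2 * 4)  # 2x2 lineage pairs x 4 classes
  expect_true(all(pw$median == 0))
})

test_that("injected shifts show up in every OP x CP lineage pair", {
  cfg <- quick_cfg(8, n_genes = 1500)
  foc <- simulate_counts(cfg)
  f <- tmm_factors(round(foc$counts))
  cm <- cpm(foc$counts, f)
  keep <- filter_expressed(cm, 1, 8)$keep
  avg <- average_two_stage(cm[keep, ], foc$metadata)
  ct <- data.frame(gene_id = foc$truth$gene_id, class = foc$truth$class)
  pw <- pairwise_lineage_ratios(avg$lineage, "parthenogenetic_female", ct)
  fpos <- pw$median[pw$class == "F"] - pw$median[pw$class == "unbiased"]
  expect_equal(length(fpos), 16)
  expect_true(all(fpos > 0))
})

test_that("the leave-one-out check is deterministic and covers each CP lineage", {
  cfg <- quick_cfg(10, n_genes = 500)
  foc <- simulate_counts(cfg)
  loo1 <- leave_one_out_check(foc$counts, foc$metadata)
  loo2 <- leave_one_out_check(foc$counts, foc$metadata)
  expect_identical(loo1, loo2)
  expect_equal(sort(unique(loo1$fold)), paste0("CP", 1:4))
  expect_true(all(c("morph", "class", "median", "p_value") %in% names(loo1)))
  # a fold lacking a morph is an error
  meta2 <- foc$metadata[!(foc$metadata$lineage == "CP1" &
                          foc$metadata$morph == "sexual_female"), ]
  expect_error(
    leave_one_out_check(foc$counts[, meta2$sample_id], meta2),
    "lacks a morph")
})
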
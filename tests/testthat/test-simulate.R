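test_that("simulators are byte-reproducible under a fixed seed", {
  cfg <- quick_cfg(7, n_genes = 300)
  expect_identical(simulate_counts(cfg), simulate_counts(cfg))
  expect_identical(simulate_outgroup(cfg), simulate_outgroup(cfg))
  gcfg <- genotype_sim_config(n_snps = 200, seed = 7)
  expect_identical(simulate_genotypes(gcfg), simulate_genotypes(gcfg))
})

test_that("focal and outgroup generators share the gene-level truth", {
  cfg <- quick_cfg(3, n_genes = 250)
  foc <- simulate_counts(cfg)
  og <- simulate_outgroup(cfg)
  expect_identical(foc$truth$gene_id, og$truth$gene_id)
  expect_identical(foc$truth$class, og$truth$class)
  expect_identical(foc$truth$tissue_bias, og$truth$tissue_bias)
})

test_that("the simulated design matches the study layout", {
  cfg <- quick_cfg(1, n_genes = 100)
  foc <- simulate_counts(cfg)
  expect_equal(ncol(foc$counts), 40L)
  m <- foc$metadata
  expect_equal(sort(unique(m$morph[m$mode == "CP"])),
               sort(c("male", "sexual_female", "parthenogenetic_female")))
  expect_equal(sort(unique(m$morph[m$mode == "OP"])),
               sort(c("male", "parthenogenetic_female")))
  expect_equal(length(unique(m$lineage)), 8L)
  og <- simulate_outgroup(cfg)
  expect_equal(ncol(og$body$counts), 6L)
  expect_equal(ncol(og$tissue$counts), 18L)
  expect_equal(sort(unique(og$tissue$metadata$tissue)),
               sort(c("head", "legs", "gonads")))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(frac_class = c(M = 0.5, F = 0.5, P = 0.5,
                                         unbiased = 0.5)), "sum to 1")
  expect_error(sim_config(frac_x_linked = 1.5), "\\[0,1\\]")
  expect_error(sim_config(n_genes = 0), ">= 1")
  expect_error(genotype_sim_config(divergence_within_mode = -1), ">= 0")
  expect_error(simulate_genotypes(list()), "genotype_sim_config")
})

test_that("simulated counts follow the NB mean-variance law", {
  set.seed(11)
  n <- 1e4
  y <- morphshift:::.draw_library(rep(0, n), rep(0.1, n), n * 50)
  expect_lt(abs(mean(y) - 50) / 50, 0.05)
  expect_lt(abs(var(y) - (50 + 0.1 * 50^2)) / (50 + 0.1 * 50^2), 0.15)
})

test_that("morph and tissue effects appear in the outgroup at the set size", {
  cfg <- quick_cfg(5, n_genes = 1200, lfc_bias = 2, lfc_limited_frac = 0,
                   frac_silent = 0)
  og <- simulate_outgroup(cfg)
  tr <- og$truth
  cm <- cpm(og$body$counts)
  meta <- og$body$metadata
  morph_mean <- average_expression(cm, meta, "morph")
  # male-biased genes: ~4x in males vs parthenogenetic females
  mb <- tr$class == "M" & tr$baseline_log2 > 3
  lr <- log2((morph_mean[mb, "male"] + .5) /
             (morph_mean[mb, "parthenogenetic_female"] + .5))
  expect_lt(abs(mean(lr) - 2), 0.25)
  # gonad-biased genes: gonad mean above head and legs in their own morph
  tm <- cpm(og$tissue$counts)
  tmeta <- og$tissue$metadata
  sel <- tmeta$morph == "male"
  tis_mean <- average_expression(tm[, tmeta$sample_id[sel]], tmeta[sel, ],
                                 "tissue")
  gb <- tr$class == "M" & tr$tissue_bias == "gonads" & tr$baseline_log2 > 3
  expect_gt(mean(log2((tis_mean[gb, "gonads"] + .5) /
                      (tis_mean[gb, "head"] + .5))), 1)
  expect_gt(mean(log2((tis_mean[gb, "gonads"] + .5) /
                      (tis_mean[gb, "legs"] + .5))), 1)
})

test_that("a null shift specification injects no OP-to-CP effect", {
  cfg <- quick_cfg(2, n_genes = 200, shift_spec = NULL)
  foc <- simulate_counts(cfg)
  expect_true(all(foc$truth$delta_male == 0))
  expect_true(all(foc$truth$delta_parthenogenetic_female == 0))
})

test_that("zero genotype drift yields identical lineages and zero Nei distance", {
  gcfg <- genotype_sim_config(n_snps = 300, divergence_within_mode = 0,
                              divergence_between_mode = 0, seed = 9)
  g <- simulate_genotypes(gcfg)
  expect_true(all(g$genotype %in% 0:2))
  expect_true(all(g$genotype == g$genotype[, 1]))
  d <- nei_distance(g$genotype)
  expect_true(all(d == 0))
})
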
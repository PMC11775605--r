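test_that("variant filtering applies GQ strictly and DP inclusively", {
  mk <- function(gq, dp) list(
    genotype = matrix(1L, 3, 2, dimnames = list(paste0("s", 1:3), c("a", "b"))),
    gq = matrix(gq, 3, 2), dp = matrix(dp, 3, 2))
  p <- variant_filter_params(min_gq = 20, min_depth = 80)
  # GQ 21 and DP 80 everywhere: retained
  expect_equal(filter_variants(mk(21, 80), p)$n_retained, 3L)
  # GQ exactly 20 ("above 20" is strict): dropped
  expect_equal(filter_variants(mk(20, 100), p)$n_retained, 0L)
  # one library at DP 79: dropped
  x <- mk(50, 100); x$dp[2, 2] <- 79
  fv <- filter_variants(x, p)
  expect_equal(fv$n_retained, 2L)
  expect_false("s2" %in% rownames(fv$genotype))
  expect_error(filter_variants(list(genotype = x$genotype), p), "GT/DP/GQ")
})

test_that("VCF round trip preserves genotypes and excludes non-SNP records", {
  g <- simulate_genotypes(genotype_sim_config(n_snps = 40, seed = 3))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(g, path)
  # append a multi-allelic record and an indel: both must be excluded
  lines <- readLines(path)
  extra <- c(
    "A1\t99991\tmulti\tA\tG,T\t.\tPASS\t.\tGT:DP:GQ\t1/2:99:99\t0/0:99:99\t0/0:99:99\t0/0:99:99\t0/0:99:99\t0/0:99:99\t0/0:99:99\t0/0:99:99",
    "A1\t99992\tindel\tAT\tA\t.\tPASS\t.\tGT:DP:GQ\t0/1:99:99\t0/0:99:99\t0/0:99:99\t0/0:99:99\t0/0:99:99\t0/0:99:99\t0/0:99:99\t0/0:99:99")
  writeLines(c(lines, extra), path)
  back <- read_genotypes_vcf(path)
  expect_equal(nrow(back$genotype), 40L)
  expect_false(any(c("multi", "indel") %in% back$snp_ids))
  expect_equal(unname(back$genotype), unname(g$genotype))
  expect_equal(unname(back$dp), unname(g$dp))
  expect_equal(unname(back$gq), unname(g$gq))
})

test_that("Nei distance matches hand arithmetic and the locus-wise oracle", {
  # one locus, frequencies 1 vs 0.5: D = -ln(0.5/sqrt(0.5)) ~ 0.3466
  d <- nei_distance(matrix(c(1, 0.5), 1, 2,
                           dimnames = list("l1", c("x", "y"))),
                    input = "frequency")
  expect_equal(d["x", "y"], 0.346573590, tolerance = 1e-9)
  set.seed(12)
  p <- matrix(runif(60 * 3), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
  d <- nei_distance(p, input = "frequency")
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(d[i, j], oracle_nei(p[, i], p[, j]), tolerance = 1e-12)
  # symmetry, zero diagonal, non-negativity
  expect_equal(d, t(d), ignore_attr = TRUE)
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
  # identical lineages
  dd <- nei_distance(cbind(a = p[, 1], b = p[, 1]), input = "frequency")
  expect_equal(dd["a", "b"], 0)
  # no shared alleles: infinite distance reported explicitly
  di <- nei_distance(matrix(c(1, 0), 1, 2, dimnames = list(NULL, c("x", "y"))),
                     input = "frequency")
  expect_equal(di["x", "y"], Inf)
})

test_that("neighbour joining recovers additive matrices exactly", {
  set.seed(13)
  tr <- ape::rtree(6)
  d <- cophenetic(tr)
  nj <- nj_tree(d)
  expect_equal(cophenetic(nj)[rownames(d), colnames(d)], d, tolerance = 1e-8)
  expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0, ignore_attr = TRUE)
  # three taxa: closed-form branch lengths from d12=3, d13=4, d23=5
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
  expect_error(nj_tree(matrix(c(0, Inf, Inf, 0), 2, 2)), "3 taxa")
})

test_that("NJ and UPGMA topologies agree on ultrametric distances", {
  set.seed(14)
  x <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(paste0("t", 1:5), NULL))
  hc <- stats::hclust(dist(x), method = "average")
  d <- cophenetic(hc)
  nj <- nj_tree(as.matrix(d))
  up <- ape::as.phylo(hc)
  expect_equal(ape::dist.topo(ape::unroot(up), nj), 0, ignore_attr = TRUE)
})

test_that("bootstrap support is seeded and finds clean mode splits", {
  g <- simulate_genotypes(genotype_sim_config(
    n_snps = 400, divergence_within_mode = 0.02,
    divergence_between_mode = 0.3, seed = 15))
  b1 <- bootstrap_support(g$genotype, n_boot = 60, seed = 2)
  b2 <- bootstrap_support(g$genotype, n_boot = 60, seed = 2)
  expect_identical(b1$support, b2$support)
  expect_equal(bipartition_support(b1, paste0("OP", 1:4)), 100)
})

test_that("genotype PCA matches an eigendecomposition oracle", {
  # variation along a single direction
  g1 <- outer(c(1, 2, 1, 0), c(1, 1, 2, 2, 3))
  rownames(g1) <- paste0("s", 1:4)
  colnames(g1) <- paste0("l", 1:5)
  p1 <- genotype_pca(g1)
  expect_equal(p1$variance_fraction[1], 1)
  # duplicated lineage: coincident coordinates
  set.seed(16)
  g2 <- matrix(sample(0:2, 50 * 4, TRUE), 50, 4,
               dimnames = list(NULL, c("a", "b", "c", "a2")))
  g2[, "a2"] <- g2[, "a"]
  p2 <- genotype_pca(g2)
  expect_equal(p2$coordinates["a", ], p2$coordinates["a2", ],
               ignore_attr = TRUE)
  # variance fractions against eigen() on the covariance matrix
  ev <- eigen(cov(t(g2)), symmetric = TRUE)$values
  expect_equal(p2$variance_fraction[1:3], (ev / sum(ev))[1:3],
               tolerance = 1e-10)
  expect_error(genotype_pca(matrix(1, 5, 3)), "constant")
})

test_that("transcriptomic distance standardizes per gene", {
  e0 <- matrix(c(5, 8, 5, 8), 2, 2, dimnames = list(c("g1", "g2"),
                                                    c("l1", "l2")))
  expect_equal(transcriptomic_distance(e0, "none")["l1", "l2"], 0)
  # pre-standardized genes differing by (3, 4): Euclidean distance 5
  e1 <- matrix(c(0, 0, 3, 4), 2, 2, dimnames = list(c("g1", "g2"),
                                                    c("l1", "l2")))
  expect_equal(transcriptomic_distance(e1, "none")["l1", "l2"], 5)
  # rescaling any gene's raw CPM leaves z-scored distances unchanged
  set.seed(17)
  e2 <- matrix(rlnorm(40 * 5, 3, 1), 40, 5,
               dimnames = list(sprintf("g%d", 1:40), paste0("l", 1:5)))
  d2 <- transcriptomic_distance(e2, "zscore")
  d2b <- transcriptomic_distance(e2 * 2, "zscore")
  expect_equal(d2, d2b)
  e3 <- rbind(e2, flat = rep(4, 5))
  expect_warning(d3 <- transcriptomic_distance(e3, "zscore"), "zero-variance")
  expect_equal(d3, d2)
})

test_that("the Mantel test is rank-invariant, seeded and label-checked", {
  set.seed(18)
  x <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(paste0("l", 1:8), NULL))
  d1 <- as.matrix(dist(x))
  mt <- mantel_test(d1, d1, n_perm = 99)
  expect_equal(mt$statistic, 1)
  # monotone nonlinear transform preserves the Spearman statistic
  mt2 <- mantel_test(d1, d1^3, n_perm = 99)
  expect_equal(mt2$statistic, 1)
  y <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(paste0("l", 1:8), NULL))
  d2 <- as.matrix(dist(y))
  a <- mantel_test(d1, d2, n_perm = 199, seed = 5)
  b <- mantel_test(d1, d2, n_perm = 199, seed = 5)
  expect_identical(a, b)
  d3 <- d2
  rownames(d3) <- colnames(d3) <- paste0("x", 1:8)
  expect_error(mantel_test(d1, d3), "labels")
})

test_that("focal mode divergence uses the exact Mann-Whitney distribution", {
  labs <- c(paste0("CP", 1:4), paste0("OP", 1:4))
  modes <- setNames(substr(labs, 1, 2), labs)
  # clean separation: all CP pair distances below all OP pair distances
  d <- matrix(0, 8, 8, dimnames = list(labs, labs))
  vals_cp <- c(1, 2, 3, 4, 5, 6) / 10
  vals_op <- c(11, 12, 13, 14, 15, 16) / 10
  ii <- which(upper.tri(d[1:4, 1:4]), arr.ind = TRUE)
  for (k in seq_len(nrow(ii))) {
    d[ii[k, 1], ii[k, 2]] <- d[ii[k, 2], ii[k, 1]] <- vals_cp[k]
    d[ii[k, 1] + 4, ii[k, 2] + 4] <- d[ii[k, 2] + 4, ii[k, 1] + 4] <- vals_op[k]
  }
  d[1:4, 5:8] <- d[5:8, 1:4] <- 0.8
  fd <- focal_mode_divergence(d, modes)
  expect_equal(fd$p_value, 2 / 70, tolerance = 1e-12)
  expect_equal(fd$p_value,
               oracle_mw_p(fd$per_lineage$mean[fd$per_lineage$mode == "CP"],
                           fd$per_lineage$mean[fd$per_lineage$mode == "OP"]))
  # correction by a proportional matrix flattens everything: p in the
  # null acceptance region
  fd2 <- focal_mode_divergence(d, modes, correct_by = d / 5)
  expect_gt(fd2$p_value, 0.99)
  expect_error(focal_mode_divergence(d, modes, correct_by = d3 <- {
    dd <- d; rownames(dd) <- colnames(dd) <- paste0("x", 1:8); dd
  }), "genetic pair")
})
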
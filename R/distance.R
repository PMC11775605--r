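## Genetic relationships (SNP filtering, Nei 1972 distance, neighbour
## joining with locus bootstrap, PCA) and transcriptomic divergence
## between reproductive modes (per-gene standardized Euclidean distances,
## Mantel tests, focal-lineage averages with Mann-Whitney comparison).

#' Variant filter thresholds
#'
#' @param min_gq genotype quality threshold (strict `>`, i.e. "above 20").
#' @param min_depth per-genotype depth threshold (inclusive `>=`).
#' @param require_all_samples keep a SNP only if every library passes
#'   both thresholds.
#' @return list of class `variant_filter_params`.
#' @export
variant_filter_params <- function(min_gq = 20, min_depth = 80,
                                  require_all_samples = TRUE) {
  if (min_gq < 0 || min_depth < 0) stop("thresholds must be >= 0", call. = FALSE)
  structure(list(min_gq = min_gq, min_depth = min_depth,
                 require_all_samples = require_all_samples),
            class = "variant_filter_params")
}

#' Filter biallelic SNP genotypes
#'
#' Accepts either a VCF path (read with vcfR; only biallelic SNP records
#' with single-base REF and ALT are considered) or a simulated genotype
#' list with `genotype`, `dp` and `gq` matrices. SNPs are retained when
#' the genotype quality is strictly above `min_gq` and the depth at
#' least `min_depth` in every library.
#'
#' @param x VCF file path or a list as returned by [simulate_genotypes()].
#' @param params a [variant_filter_params()].
#' @return list with `genotype` (retained SNP x lineage dosage matrix),
#'   `lineage_ids`, `n_input` and `n_retained`.
#' @export
filter_variants <- function(x, params = variant_filter_params()) {
  if (is.character(x)) x <- read_genotypes_vcf(x)
  if (!all(c("genotype", "dp", "gq") %in% names(x)))
    stop("missing GT/DP/GQ fields", call. = FALSE)
  geno <- x$genotype
  ok <- x$gq > params$min_gq & x$dp >= params$min_depth & !is.na(geno)
  keep <- if (params$require_all_samples) rowSums(ok) == ncol(geno)
          else rowSums(ok) > 0
  list(genotype = geno[keep, , drop = FALSE],
       lineage_ids = colnames(geno),
       n_input = nrow(geno), n_retained = sum(keep))
}

#' Nei (1972) standard genetic distance
#'
#' `D = -ln( Jxy / sqrt(Jx * Jy) )` where `Jx`, `Jy` and `Jxy` are the
#' within- and between-population probabilities of allelic identity
#' averaged across loci. For biallelic SNPs with one diploid individual
#' per lineage, allele frequencies are dosage/2 (a heterozygote
#' contributes frequency 0.5). Identical lineages have distance zero;
#' a pair sharing no alleles anywhere has infinite distance.
#'
#' @param x SNP x lineage matrix: alt-allele dosages in 0/1/2
#'   (`input = "dosage"`) or alt-allele frequencies in \[0, 1\]
#'   (`input = "frequency"`).
#' @param input interpretation of `x`.
#' @return symmetric labeled distance matrix with zero diagonal and
#'   attribute `kind = "genetic"`.
#' @export
nei_distance <- function(x, input = c("dosage", "frequency")) {
  input <- match.arg(input)
  p <- if (input == "dosage") as.matrix(x) / 2 else as.matrix(x)
  if (any(p < 0 | p > 1)) stop("allele frequencies outside [0, 1]", call. = FALSE)
  n <- ncol(p)
  q <- 1 - p
  J <- crossprod(p) / nrow(p) + crossprod(q) / nrow(p)  # identity probabilities
  d <- matrix(0, n, n, dimnames = list(colnames(p), colnames(p)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d[i, j] <- -log(J[i, j] / sqrt(J[i, i] * J[j, j]))
  }
  d[d < 0 & d > -1e-12] <- 0
  attr(d, "kind") <- "genetic"
  d
}

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration (via [ape::nj()]); reproduces additive
#' distance matrices exactly.
#'
#' @param d symmetric labeled distance matrix (finite entries, >= 3 taxa).
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  ape::nj(as.dist(d))
}

#' Bootstrap support for the neighbour-joining tree
#'
#' Resamples SNP loci with replacement, rebuilds the Nei/NJ tree, and
#' reports for each internal edge of the full-data tree the percentage
#' of bootstrap trees containing the same bipartition.
#'
#' @param genotype SNP x lineage dosage matrix.
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed (supports are deterministic given the seed).
#' @return list with `tree` (node labels = supports), `support` (per
#'   internal node, percent), `boot_trees` and `n_boot`.
#' @export
bootstrap_support <- function(genotype, n_boot = 1000, seed = 1L) {
  if (ncol(genotype) < 4L) stop("need at least 4 taxa", call. = FALSE)
  main <- nj_tree(nei_distance(genotype))
  set.seed(seed)
  boot_trees <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(genotype), replace = TRUE)
    boot_trees[[b]] <- nj_tree(nei_distance(genotype[idx, , drop = FALSE]))
  }
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(main, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / n_boot * 100
  main$node.label <- support
  list(tree = main, support = support, boot_trees = boot_trees,
       n_boot = n_boot)
}

#' Bootstrap support for a specific bipartition
#'
#' Fraction of bootstrap trees in which `tips` (e.g. the OP lineages)
#' form one side of a bipartition.
#'
#' @param boot result of [bootstrap_support()].
#' @param tips character tip labels of one side.
#' @return support in percent.
#' @export
bipartition_support <- function(boot, tips) {
  hit <- vapply(boot$boot_trees, function(tr) {
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    any(vapply(pp, function(s) {
      side <- sort(labs[s])
      identical(side, sort(tips)) ||
        identical(side, sort(setdiff(labs, tips)))
    }, logical(1)))
  }, logical(1))
  mean(hit) * 100
}

#' PCA of lineage genotypes
#'
#' @param genotype SNP x lineage dosage matrix.
#' @param scale scale each SNP to unit variance (default: centered only).
#' @return list with `coordinates` (lineage x axis scores) and
#'   `variance_fraction` per axis.
#' @export
genotype_pca <- function(genotype, scale = FALSE) {
  m <- t(as.matrix(genotype))
  if (nrow(m) < 2L) stop("need at least 2 lineages", call. = FALSE)
  v <- apply(m, 2L, var)
  if (all(v == 0)) stop("constant genotype matrix", call. = FALSE)
  if (scale) m <- m[, v > 0, drop = FALSE]
  pc <- prcomp(m, center = TRUE, scale. = scale)
  list(coordinates = pc$x,
       variance_fraction = pc$sdev^2 / sum(pc$sdev^2))
}

#' Transcriptomic Euclidean distance between lineages
#'
#' Expression is standardized per gene across the compared lineages
#' (z-score by default, or centering only), then Euclidean distances are
#' computed between lineage expression vectors. Zero-variance genes are
#' dropped with a warning under z-scoring. Standardization makes the
#' distance invariant to rescaling any gene's raw CPM across lineages.
#'
#' @param expr gene x lineage CPM matrix (one morph, lineage-averaged).
#' @param standardize `"zscore"`, `"center"` or `"none"`.
#' @return symmetric labeled distance matrix, attribute
#'   `kind = "transcriptomic"`.
#' @export
transcriptomic_distance <- function(expr,
                                    standardize = c("zscore", "center", "none")) {
  standardize <- match.arg(standardize)
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("need at least 2 lineages", call. = FALSE)
  if (standardize != "none") {
    mu <- rowMeans(expr)
    expr <- expr - mu
    if (standardize == "zscore") {
      s <- apply(expr, 1L, sd)
      drop <- s == 0
      if (any(drop)) {
        warning(sum(drop), " zero-variance gene(s) dropped")
        expr <- expr[!drop, , drop = FALSE]
        s <- s[!drop]
      }
      expr <- expr / s
    }
  }
  d <- as.matrix(dist(t(expr)))
  attr(d, "kind") <- "transcriptomic"
  d
}

#' Mantel test between two distance matrices
#'
#' Spearman (rank) correlation of the lower-triangle entries, with the
#' permutation p-value of [vegan::mantel()]; seeded for reproducibility.
#'
#' @param d1,d2 symmetric labeled distance matrices over the same labels.
#' @param method correlation method (default `"spearman"`).
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return list with `statistic` (r), `p_value` and `n_perm`.
#' @export
mantel_test <- function(d1, d2, method = "spearman", n_perm = 999, seed = 1L) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (is.null(rownames(d1)) || is.null(rownames(d2)) ||
      !setequal(rownames(d1), rownames(d2)))
    stop("distance matrix labels do not match", call. = FALSE)
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  d2 <- d2[rownames(d1), rownames(d1)]
  set.seed(seed)
  mt <- vegan::mantel(as.dist(d1), as.dist(d2), method = method,
                      permutations = n_perm)
  list(statistic = unname(mt$statistic), p_value = mt$signif, n_perm = n_perm)
}

#' Focal-lineage divergence and Mann-Whitney comparison between modes
#'
#' For each focal lineage, averages its pairwise values (distances, or
#' transcriptomic-to-genetic distance ratios when `correct_by` is given)
#' with the other lineages of the same reproductive mode, then compares
#' the two sets of focal means with an exact two-sided Mann-Whitney test.
#'
#' @param d symmetric labeled distance matrix.
#' @param modes named character vector: reproductive mode per lineage
#'   label (exactly two modes).
#' @param correct_by optional genetic distance matrix over the same
#'   labels; values become `d / correct_by` per pair.
#' @return list with `per_lineage` (data.frame lineage, mode, mean),
#'   `mode_means`, `statistic` (Mann-Whitney U) and `p_value`.
#' @export
focal_mode_divergence <- function(d, modes, correct_by = NULL) {
  d <- as.matrix(d)
  labs <- rownames(d)
  if (!all(labs %in% names(modes)))
    stop("modes must be named by the distance labels", call. = FALSE)
  modes <- modes[labs]
  if (length(unique(modes)) != 2L) stop("need exactly two modes", call. = FALSE)
  v <- d
  if (!is.null(correct_by)) {
    g <- as.matrix(correct_by)
    if (is.null(rownames(g)) || !all(labs %in% rownames(g)))
      stop("missing genetic pair for correction", call. = FALSE)
    g <- g[labs, labs]
    v <- d / g
    diag(v) <- 0
  }
  per <- data.frame(lineage = labs, mode = unname(modes),
                    mean = vapply(labs, function(l) {
                      same <- labs[modes == modes[l] & labs != l]
                      mean(v[l, same])
                    }, numeric(1)), row.names = NULL,
                    stringsAsFactors = FALSE)
  ms <- sort(unique(per$mode))
  x <- per$mean[per$mode == ms[1]]
  y <- per$mean[per$mode == ms[2]]
  exact <- !any(duplicated(c(x, y)))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  pv <- wt$p.value
  if (is.nan(pv)) pv <- 1  # complete ties carry no evidence either way
  mode_means <- setNames(c(mean(x), mean(y)), ms)
  list(per_lineage = per, mode_means = mode_means,
       statistic = unname(wt$statistic), p_value = pv)
}
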
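## Genewise two-group negative-binomial exact tests with a single common
## dispersion, as classically paired with small-replicate RNA-seq designs.
## Counts are mapped to a common effective library size with a
## quantile-mapping adjustment (mean of a normal and a gamma quantile
## transform); the test then conditions on the per-gene pseudo-count
## total: under a common dispersion the group totals are themselves
## negative binomial, and the two-sided p-value is min(1, 2 x smaller
## tail mass) of the conditional distribution of the group-A total.

## Quantile mapping of counts between library sizes under a NB model.
## Identity when input.mean == output.mean.
.q2qnbinom <- function(x, input.mean, output.mean, dispersion = 0) {
  zero <- input.mean < 1e-14 | output.mean < 1e-14
  input.mean[zero] <- input.mean[zero] + 0.25
  output.mean[zero] <- output.mean[zero] + 0.25
  ri <- 1 + dispersion * input.mean
  vi <- input.mean * ri
  ro <- 1 + dispersion * output.mean
  vo <- output.mean * ro
  q1 <- output.mean + sqrt(vo / vi) * (x - input.mean)
  # gamma quantile map, switching tails at the mean to keep precision
  pL <- pgamma(x, shape = input.mean / ri, scale = ri)
  qL <- qgamma(pL, shape = output.mean / ro, scale = ro)
  pU <- pgamma(x, shape = input.mean / ri, scale = ri, lower.tail = FALSE)
  qU <- qgamma(pU, shape = output.mean / ro, scale = ro, lower.tail = FALSE)
  q2 <- qL
  hi <- x > input.mean
  q2[hi] <- qU[hi]
  (q1 + q2) / 2
}

## Equalize a count matrix to the geometric-mean effective size.
.equalize_counts <- function(counts, sizes, dispersion) {
  common <- exp(mean(log(sizes)))
  lambda <- rowSums(counts) / sum(sizes)
  input.mean <- outer(lambda, sizes)
  output.mean <- matrix(lambda * common, nrow(counts), ncol(counts))
  ps <- .q2qnbinom(counts, input.mean, output.mean, dispersion)
  ps[ps < 0] <- 0
  ps
}

## Conditional NB log-likelihood (terms in the dispersion only), one group.
.cond_loglik_group <- function(Y, r) {
  n <- ncol(Y)
  z <- rowSums(Y)
  rowSums(lgamma(Y + r)) - n * lgamma(r) + lgamma(n * r) - lgamma(z + n * r)
}

#' Common negative-binomial dispersion by conditional maximum likelihood
#'
#' Estimates a single dispersion shared by all genes by maximizing the
#' conditional (on per-gene group totals) NB likelihood summed over
#' genes, after mapping counts to a common effective library size by
#' quantile adjustment. The equalization and maximization are iterated
#' twice so the pseudo-counts reflect the estimated dispersion.
#'
#' @param counts integer gene x sample matrix.
#' @param groups factor/vector assigning samples to groups.
#' @param lib_size effective library sizes (library size x TMM factor);
#'   defaults to column sums.
#' @param interval search interval for the dispersion.
#' @return non-negative dispersion estimate (phi; variance = mu + phi mu^2).
#' @export
estimate_common_dispersion <- function(counts, groups, lib_size = NULL,
                                       interval = c(1e-6, 4)) {
  counts <- as.matrix(counts)
  if (max(abs(counts - round(counts))) > 1e-8)
    stop("counts must be integers; round fractional counts upstream",
         call. = FALSE)
  if (all(counts == 0)) stop("all-zero count matrix", call. = FALSE)
  if (is.null(lib_size)) lib_size <- colSums(counts)
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts))
    stop("groups must align with samples", call. = FALSE)
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  obj <- function(phi, ps) {
    r <- 1 / phi
    sum(vapply(levels(groups), function(g) {
      sum(.cond_loglik_group(ps[, groups == g, drop = FALSE], r))
    }, numeric(1)))
  }
  phi <- 0.01
  for (it in 1:2) {
    ps <- .equalize_counts(counts, lib_size, phi)
    opt <- optimize(obj, interval = interval, ps = ps, maximum = TRUE)
    # boundary check: a Poisson-like fit is better served by the lower bound
    if (obj(interval[1], ps) >= opt$objective) phi <- interval[1]
    else phi <- opt$maximum
  }
  phi
}

## Two-sided conditional exact p for group-A total a out of grand total t,
## with nA and nB libraries at equal effective sizes and dispersion phi.
.cond_exact_p <- function(a, t, nA, nB, phi) {
  if (t == 0) return(1)
  ks <- 0:t
  if (phi <= 0) {
    logw <- dbinom(ks, t, nA / (nA + nB), log = TRUE)
  } else {
    muA <- t * nA / (nA + nB)
    muB <- t * nB / (nA + nB)
    logw <- dnbinom(ks, size = nA / phi, mu = muA, log = TRUE) +
      dnbinom(t - ks, size = nB / phi, mu = muB, log = TRUE)
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  lower <- sum(w[ks <= a])
  upper <- sum(w[ks >= a])
  min(1, 2 * min(lower, upper))
}

#' Genewise negative-binomial exact test between two groups
#'
#' Counts are quantile-adjusted to a common effective library size and
#' rounded to integers; conditioning on the per-gene pseudo-count total,
#' the two-sided p-value is min(1, 2 x smaller tail mass) of the
#' conditional distribution of the group-A total. The fold change is
#' computed on the CPM scale as log2 of the group-B-to-group-A mean with
#' a small proportional prior count to avoid log of zero.
#'
#' @param countsA,countsB integer gene x sample matrices for the two
#'   groups (vectors are treated as single genes).
#' @param sizesA,sizesB positive effective library sizes.
#' @param dispersion common NB dispersion (phi >= 0).
#' @param prior_count prior count (at the geometric-mean library size)
#'   added to each group mean CPM for the fold-change estimate.
#' @return data.frame (`gene_id`, `log2_fold_change`, `p_value`, `adj_p`)
#'   with `adj_p` the Benjamini-Hochberg adjusted p-value.
#' @export
nb_exact_test <- function(countsA, countsB, sizesA = NULL, sizesB = NULL,
                          dispersion = 0, prior_count = 2) {
  if (is.null(dim(countsA))) countsA <- matrix(countsA, nrow = 1)
  if (is.null(dim(countsB))) countsB <- matrix(countsB, nrow = 1)
  if (nrow(countsA) != nrow(countsB))
    stop("gene sets of the two groups differ", call. = FALSE)
  if (max(abs(countsA - round(countsA))) > 1e-8 ||
      max(abs(countsB - round(countsB))) > 1e-8)
    stop("counts must be integers; round fractional counts upstream",
         call. = FALSE)
  if (is.null(sizesA)) sizesA <- colSums(countsA)
  if (is.null(sizesB)) sizesB <- colSums(countsB)
  if (any(c(sizesA, sizesB) <= 0)) stop("sizes must be positive", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  nA <- ncol(countsA); nB <- ncol(countsB)
  sizes <- c(sizesA, sizesB)
  common <- exp(mean(log(sizes)))
  joint <- cbind(countsA, countsB)
  ps <- .equalize_counts(joint, sizes, dispersion)
  a <- round(rowSums(ps[, seq_len(nA), drop = FALSE]))
  b <- round(rowSums(ps[, nA + seq_len(nB), drop = FALSE]))
  p <- vapply(seq_along(a), function(g) {
    .cond_exact_p(a[g], a[g] + b[g], nA, nB, dispersion)
  }, numeric(1))
  prior_cpm <- prior_count / common * 1e6
  cpmA <- rowMeans(sweep(countsA, 2L, sizesA, "/")) * 1e6
  cpmB <- rowMeans(sweep(countsB, 2L, sizesB, "/")) * 1e6
  lfc <- log2((cpmB + prior_cpm) / (cpmA + prior_cpm))
  gene_id <- rownames(countsA)
  if (is.null(gene_id)) gene_id <- sprintf("gene%d", seq_along(a))
  data.frame(gene_id = gene_id, log2_fold_change = lfc, p_value = p,
             adj_p = bh_adjust(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 (wraps [stats::p.adjust()]).
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}
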
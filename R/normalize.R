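## TMM normalization, CPM, expression filtering and replicate/lineage
## averaging. The TMM implementation follows the canonical published
## algorithm: reference sample chosen by the upper-quantile rule
## (p = 0.75), per-sample factor = 2^(precision-weighted doubly trimmed
## mean of M-values against the reference over genes expressed in both),
## factors rescaled to geometric mean 1.

#' TMM normalization factors
#'
#' @param counts non-negative gene x sample matrix (fractional counts are
#'   accepted; normalization is count-scale-free).
#' @param lib_size per-sample library sizes; defaults to column sums.
#' @param ref_quantile quantile used to pick the reference sample (the one
#'   whose upper-quantile/library-size ratio is closest to the mean ratio).
#' @param logratio_trim two-sided trim fraction on M-values.
#' @param abs_trim two-sided trim fraction on A-values (average abundance).
#' @param do_weighting use inverse asymptotic variances as weights.
#' @return named vector of strictly positive factors with geometric mean 1.
#' @export
tmm_factors <- function(counts, lib_size = NULL, ref_quantile = 0.75,
                        logratio_trim = 0.3, abs_trim = 0.05,
                        do_weighting = TRUE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (logratio_trim < 0 || logratio_trim >= 0.5 || abs_trim < 0 || abs_trim >= 0.5)
    stop("trim fractions must lie in [0, 0.5)", call. = FALSE)
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (any(lib_size <= 0)) {
    bad <- colnames(counts)[lib_size <= 0]
    stop("all-zero library: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  fq <- apply(counts, 2L, function(x) quantile(x, probs = ref_quantile)) / lib_size
  ref <- which.min(abs(fq - mean(fq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], lib_size[j], lib_size[ref],
              logratio_trim, abs_trim, do_weighting)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

## One-pair TMM factor (obs vs ref), on the 2^ scale, unscaled.
.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim,
                      do_weighting) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  keep <- is.finite(logR) & is.finite(absE) & absE > -1e10
  logR <- logR[keep]; absE <- absE[keep]; v <- v[keep]
  if (length(logR) == 0L || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * abs_trim) + 1
  hiS <- n + 1 - loS
  sel <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  f <- if (do_weighting) {
    sum(logR[sel] / v[sel], na.rm = TRUE) / sum(1 / v[sel], na.rm = TRUE)
  } else {
    mean(logR[sel], na.rm = TRUE)
  }
  if (!is.finite(f)) f <- 0
  2^f
}

#' Counts per million after TMM scaling
#'
#' `cpm = count / (library size x factor) x 1e6`.
#'
#' @param counts gene x sample matrix.
#' @param factors per-sample normalization factors (default 1); must align
#'   with the columns of `counts`.
#' @param lib_size per-sample library sizes; defaults to column sums.
#' @return gene x sample CPM matrix.
#' @export
cpm <- function(counts, factors = NULL, lib_size = NULL) {
  counts <- as.matrix(counts)
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (length(factors) != ncol(counts))
    stop("factors are not aligned with samples", call. = FALSE)
  if (!is.null(names(factors)) && !is.null(colnames(counts)) &&
      !identical(names(factors), colnames(counts))) {
    if (!all(colnames(counts) %in% names(factors)))
      stop("factors are not aligned with samples", call. = FALSE)
    factors <- factors[colnames(counts)]
  }
  if (any(factors <= 0)) stop("factors must be strictly positive", call. = FALSE)
  sweep(counts, 2L, lib_size * factors, "/") * 1e6
}

#' Filter genes on normalized expression
#'
#' Retains genes with CPM strictly greater than `cpm_threshold` in at
#' least `min_libraries` libraries (e.g. 8 of the 40 focal libraries, or
#' 2 of the 6 whole-body outgroup libraries).
#'
#' @param cpm_mat gene x sample CPM matrix.
#' @param cpm_threshold strict CPM threshold.
#' @param min_libraries minimum number of libraries exceeding it.
#' @return list with `keep` (named logical), `gene_ids` of retained genes
#'   and `n_retained`.
#' @export
filter_expressed <- function(cpm_mat, cpm_threshold = 1, min_libraries = 8L) {
  if (cpm_threshold <= 0) stop("cpm_threshold must be > 0", call. = FALSE)
  keep <- rowSums(cpm_mat > cpm_threshold) >= min_libraries
  list(keep = keep, gene_ids = rownames(cpm_mat)[keep], n_retained = sum(keep))
}

#' Group means of expression
#'
#' Arithmetic mean of CPM within each group defined by one or more
#' metadata columns. For the two-stage scheme used throughout the
#' pipeline (replicates averaged within lineage, then lineages within
#' reproductive mode) see [average_two_stage()].
#'
#' @param expr gene x sample matrix; columns must match `meta$sample_id`.
#' @param meta sample metadata with a `sample_id` column.
#' @param by character vector of metadata column names defining groups.
#' @return gene x group matrix; group names join the `by` values with ".".
#' @export
average_expression <- function(expr, meta, by) {
  if (!all(by %in% names(meta)))
    stop("grouping columns missing from metadata: ",
         paste(setdiff(by, names(meta)), collapse = ", "), call. = FALSE)
  meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata does not cover all samples", call. = FALSE)
  key <- interaction(meta[by], drop = TRUE, sep = ".", lex.order = TRUE)
  if (any(table(key) == 0L)) stop("empty group", call. = FALSE)
  groups <- levels(key)
  out <- matrix(0, nrow(expr), length(groups),
                dimnames = list(rownames(expr), groups))
  for (g in groups) out[, g] <- rowMeans(expr[, key == g, drop = FALSE])
  out
}

#' Two-stage averaging: replicates within lineage, then lineages
#'
#' First averages replicate CPMs within each (lineage, morph), then
#' averages those lineage means within each (mode, morph). With
#' unbalanced replicate values this differs from pooling all libraries of
#' a mode directly; the pipeline always uses the two-stage form.
#'
#' @param expr gene x sample CPM matrix.
#' @param meta sample metadata (`sample_id`, `lineage`, `mode`, `morph`).
#' @return list with `lineage` (gene x lineage.morph means) and `mode`
#'   (gene x mode.morph means).
#' @export
average_two_stage <- function(expr, meta) {
  lin <- average_expression(expr, meta, by = c("lineage", "morph"))
  lin_meta <- unique(meta[, c("lineage", "mode", "morph")])
  lin_meta$sample_id <- paste(lin_meta$lineage, lin_meta$morph, sep = ".")
  lin_meta <- lin_meta[match(colnames(lin), lin_meta$sample_id), ]
  mode <- average_expression(lin, lin_meta, by = c("mode", "morph"))
  list(lineage = lin, mode = mode)
}
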
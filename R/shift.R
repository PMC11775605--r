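## OP-to-CP expression shift: per-gene log2 ratio of mode-averaged CPM
## within one morph, class-wise Wilcoxon signed-rank tests against zero,
## subdivision panels, pairwise-lineage and leave-one-out robustness
## checks.

#' Shift-statistic parameters
#'
#' @param pseudocount CPM added to numerator and denominator of the
#'   OP-to-CP ratio to avoid division by zero.
#' @param morphs morphs for which the ratio is computed (the morphs
#'   present in both reproductive modes).
#' @return list of class `shift_params`.
#' @export
shift_params <- function(pseudocount = 0.05,
                         morphs = c("parthenogenetic_female", "male")) {
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  structure(list(pseudocount = pseudocount, morphs = morphs),
            class = "shift_params")
}

#' Per-gene OP-to-CP log2 expression ratio
#'
#' `ratio = log2((mean_OP + eps) / (mean_CP + eps))` for one morph, where
#' the means come from two-stage averaging (replicates within lineage,
#' then lineages within mode). Positive ratios mean higher expression in
#' OP; the statistic is antisymmetric under swapping OP and CP.
#'
#' @param mean_op,mean_cp named per-gene mean CPM vectors for the same
#'   morph in the two modes.
#' @param morph morph the means belong to (stored in the output).
#' @param params a [shift_params()].
#' @return data.frame (`gene_id`, `morph`, `ratio`).
#' @export
op_cp_ratio <- function(mean_op, mean_cp, morph, params = shift_params()) {
  if (length(mean_op) != length(mean_cp))
    stop("OP and CP mean vectors differ in length", call. = FALSE)
  if (!is.null(names(mean_op)) && !is.null(names(mean_cp)) &&
      !identical(names(mean_op), names(mean_cp)))
    stop("OP and CP gene sets differ", call. = FALSE)
  eps <- params$pseudocount
  gene_id <- names(mean_op)
  if (is.null(gene_id)) gene_id <- sprintf("gene%d", seq_along(mean_op))
  data.frame(gene_id = gene_id, morph = morph,
             ratio = log2((mean_op + eps) / (mean_cp + eps)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the shift table for one morph from mode-averaged CPM
#'
#' @param mode_means gene x group matrix from [average_two_stage()]
#'   (`$mode`), with columns named `<mode>.<morph>`.
#' @param morph morph to extract.
#' @param class_table expression class table ([classify_outgroup()]);
#'   class keys are joined onto the ratios. Genes absent from the class
#'   table are dropped (they were not classifiable on the outgroup).
#' @param params a [shift_params()].
#' @return data.frame with `gene_id`, `morph`, `ratio` and the class keys.
#' @export
shift_table <- function(mode_means, morph, class_table = NULL,
                        params = shift_params()) {
  op_col <- paste0("OP.", morph)
  cp_col <- paste0("CP.", morph)
  if (!all(c(op_col, cp_col) %in% colnames(mode_means)))
    stop("mode means lack morph ", morph, " in both modes", call. = FALSE)
  tab <- op_cp_ratio(setNames(mode_means[, op_col], rownames(mode_means)),
                     setNames(mode_means[, cp_col], rownames(mode_means)),
                     morph, params)
  if (!is.null(class_table)) {
    tab <- merge(tab, class_table, by = "gene_id", sort = FALSE)
  }
  tab
}

#' Wilcoxon signed-rank test of a gene class against zero
#'
#' Zero ratios are dropped before testing; the exact signed-rank
#' distribution is used for n <= 25 without ties in |ratio|, otherwise
#' the continuity-corrected normal approximation. The reported median is
#' over all (finite) ratios of the class.
#'
#' @param ratios per-gene log2 ratios of one class.
#' @param label class label for the output.
#' @return one-row data.frame (`class`, `n_genes`, `median`, `statistic`,
#'   `p_value`).
#' @export
wilcoxon_class_test <- function(ratios, label = "class") {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) == 0L) stop("empty class: ", label, call. = FALSE)
  x <- ratios[ratios != 0]
  if (length(x) == 0L) {
    return(data.frame(class = label, n_genes = length(ratios),
                      median = 0, statistic = NA_real_, p_value = 1,
                      stringsAsFactors = FALSE))
  }
  exact <- length(x) <= 25 && !any(duplicated(abs(x)))
  wt <- suppressWarnings(wilcox.test(x, mu = 0, exact = exact, correct = TRUE))
  data.frame(class = label, n_genes = length(ratios),
             median = median(ratios), statistic = unname(wt$statistic),
             p_value = wt$p.value, stringsAsFactors = FALSE)
}

#' Class-wise shift tests
#'
#' One Wilcoxon signed-rank test per morph-bias class (M, F, P,
#' unbiased).
#'
#' @param shift data.frame from [shift_table()] (needs `ratio`, `class`).
#' @return data.frame of [wilcoxon_class_test()] rows.
#' @export
class_shift_tests <- function(shift) {
  classes <- intersect(c("M", "F", "P", "unbiased"), unique(shift$class))
  classes <- c(classes, setdiff(sort(unique(shift$class)), classes))
  do.call(rbind, lapply(classes, function(cl) {
    wilcoxon_class_test(shift$ratio[shift$class == cl], cl)
  }))
}

#' Subdivide morph-biased classes and test each level
#'
#' For each biased class (M, F, P) and each level of the subdivision key
#' (`degree`, `chromosome_class` or `tissue_bias`), tests the OP-to-CP
#' ratios against zero. For the tissue subdivision, genes without a
#' tissue-bias call (`"none"`) are excluded from the panels; empty levels
#' are skipped with a warning.
#'
#' @param shift data.frame from [shift_table()].
#' @param by one of `"degree"`, `"chromosome_class"`, `"tissue_bias"`.
#' @return data.frame with columns `class`, `level`, `n_genes`, `median`,
#'   `statistic`, `p_value`.
#' @export
subdivide_and_test <- function(shift,
                               by = c("degree", "chromosome_class", "tissue_bias")) {
  by <- match.arg(by)
  if (!by %in% names(shift)) stop("missing class key: ", by, call. = FALSE)
  sub <- shift[shift$class %in% c("M", "F", "P"), , drop = FALSE]
  if (by == "tissue_bias") sub <- sub[sub$tissue_bias != "none", , drop = FALSE]
  if (by == "degree") sub <- sub[sub$degree != "none", , drop = FALSE]
  out <- NULL
  for (cl in intersect(c("M", "F", "P"), unique(sub$class))) {
    for (lv in sort(unique(sub[[by]][sub$class == cl]))) {
      r <- sub$ratio[sub$class == cl & sub[[by]] == lv]
      if (length(r) == 0L) {
        warning("empty subdivision level ", cl, "/", lv, "; skipped")
        next
      }
      row <- wilcoxon_class_test(r, cl)
      row$level <- lv
      out <- rbind(out, row)
    }
  }
  if (is.null(out)) return(NULL)
  out[, c("class", "level", "n_genes", "median", "statistic", "p_value")]
}

#' Pairwise OP x CP lineage ratios
#'
#' Recomputes the per-gene log2 ratio for every (OP lineage, CP lineage)
#' pair from lineage-averaged CPM and reports per-class medians,
#' checking that the class-level shift is not driven by a single lineage.
#'
#' @param lineage_means gene x `<lineage>.<morph>` matrix
#'   ([average_two_stage()] `$lineage`).
#' @param morph morph to compare.
#' @param class_table expression class table.
#' @param params a [shift_params()].
#' @return data.frame (`op_lineage`, `cp_lineage`, `class`, `n_genes`,
#'   `median`).
#' @export
pairwise_lineage_ratios <- function(lineage_means, morph, class_table,
                                    params = shift_params()) {
  cols <- colnames(lineage_means)
  sel <- grepl(paste0("\\.", morph, "$"), cols)
  lineages <- sub(paste0("\\.", morph, "$"), "", cols[sel])
  op_lin <- lineages[startsWith(lineages, "OP")]
  cp_lin <- lineages[startsWith(lineages, "CP")]
  out <- NULL
  for (ol in op_lin) for (cl_ in cp_lin) {
    tab <- op_cp_ratio(
      setNames(lineage_means[, paste0(ol, ".", morph)], rownames(lineage_means)),
      setNames(lineage_means[, paste0(cl_, ".", morph)], rownames(lineage_means)),
      morph, params)
    tab <- merge(tab, class_table[, c("gene_id", "class")], by = "gene_id",
                 sort = FALSE)
    med <- aggregate(ratio ~ class, tab, median)
    n <- aggregate(ratio ~ class, tab, length)
    out <- rbind(out, data.frame(op_lineage = ol, cp_lineage = cl_,
                                 class = med$class, n_genes = n$ratio,
                                 median = med$ratio, stringsAsFactors = FALSE))
  }
  out
}

#' Leave-one-out circularity check
#'
#' Classifies genes on each held-out CP lineage (its three morphs, two
#' replicates each, via the same exact-test classification used for the
#' outgroup) and recomputes the OP-to-CP ratios from the remaining three
#' CP lineages and all OP lineages. Reports per-fold, per-class medians;
#' agreement with the outgroup-based medians indicates the class calls
#' are not an artifact of the dataset used to define them.
#'
#' @param counts focal gene x sample count matrix (40 libraries).
#' @param meta focal sample metadata.
#' @param class_params a [classification_params()].
#' @param params a [shift_params()].
#' @param annotation optional gene annotation for chromosome class.
#' @return data.frame of class test rows with columns `fold` (held-out
#'   CP lineage), `morph`, `class`, `n_genes`, `median`, `statistic`,
#'   `p_value`.
#' @export
leave_one_out_check <- function(counts, meta,
                                class_params = classification_params(),
                                params = shift_params(),
                                annotation = NULL) {
  counts <- as.matrix(counts)
  f <- tmm_factors(round(counts))
  cpm_mat <- cpm(counts, f)
  cp_lineages <- sort(unique(meta$lineage[meta$mode == "CP"]))
  out <- NULL
  for (fold in cp_lineages) {
    sel <- meta$lineage == fold
    morphs_here <- unique(meta$morph[sel])
    if (length(morphs_here) < 3L)
      stop("fold ", fold, " lacks a morph", call. = FALSE)
    body <- list(counts = counts[, meta$sample_id[sel], drop = FALSE],
                 metadata = meta[sel, , drop = FALSE])
    ct <- classify_outgroup(body, tissue = NULL, annotation = annotation,
                            params = class_params)
    rest <- meta[!sel, , drop = FALSE]
    avg <- average_two_stage(cpm_mat[, rest$sample_id, drop = FALSE], rest)
    for (m in params$morphs) {
      st <- shift_table(avg$mode, m, ct, params)
      res <- do.call(rbind, lapply(sort(unique(st$class)), function(cl)
        wilcoxon_class_test(st$ratio[st$class == cl], cl)))
      res$fold <- fold
      res$morph <- m
      out <- rbind(out, res)
    }
  }
  out[, c("fold", "morph", "class", "n_genes", "median", "statistic", "p_value")]
}
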
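## Morph-bias and tissue-bias classification. A gene is biased towards a
## morph (or tissue) when it is significantly overexpressed by that morph
## in BOTH pairwise comparisons with the two other morphs (adjusted
## p < alpha and |log2FC| > lfc_biased, strict inequalities), and
## morph-limited when additionally |log2FC| > lfc_limited in both.

#' Classification thresholds
#'
#' @param alpha adjusted-p threshold (strict `<`).
#' @param lfc_biased absolute log2 fold-change threshold for "biased"
#'   (strict `>`).
#' @param lfc_limited absolute log2 fold-change threshold for "limited".
#' @return list of class `classification_params`.
#' @export
classification_params <- function(alpha = 0.05, lfc_biased = 1, lfc_limited = 2) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (!(lfc_limited > lfc_biased && lfc_biased > 0))
    stop("need lfc_limited > lfc_biased > 0", call. = FALSE)
  structure(list(alpha = alpha, lfc_biased = lfc_biased,
                 lfc_limited = lfc_limited), class = "classification_params")
}

#' Pairwise exact tests among the levels of a grouping variable
#'
#' Runs [nb_exact_test()] for every unordered pair of levels, with a
#' common dispersion estimated on the whole matrix by
#' [estimate_common_dispersion()]. Fractional counts are rounded to the
#' nearest integer first (the conditional NB distribution requires
#' integers).
#'
#' @param counts gene x sample count matrix.
#' @param groups vector assigning each sample to a level (e.g. morph or
#'   tissue).
#' @param lib_size effective library sizes; defaults to column sums times
#'   TMM factors computed here.
#' @param params a [classification_params()] (unused for testing itself;
#'   kept for interface symmetry).
#' @return named list of test data.frames; each carries attributes
#'   `groupA` and `groupB`, with `log2_fold_change` the B-to-A log2 ratio.
#' @export
pairwise_exact_tests <- function(counts, groups, lib_size = NULL,
                                 params = classification_params()) {
  counts <- round(as.matrix(counts))
  groups <- as.character(groups)
  if (is.null(lib_size)) {
    f <- tmm_factors(counts)
    lib_size <- colSums(counts) * f
  }
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least two groups", call. = FALSE)
  phi <- estimate_common_dispersion(counts, groups, lib_size = lib_size)
  pairs <- utils::combn(lev, 2L, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    selA <- groups == pr[1]
    selB <- groups == pr[2]
    res <- nb_exact_test(counts[, selA, drop = FALSE],
                         counts[, selB, drop = FALSE],
                         sizesA = lib_size[selA], sizesB = lib_size[selB],
                         dispersion = phi)
    attr(res, "groupA") <- pr[1]
    attr(res, "groupB") <- pr[2]
    res
  })
  names(out) <- vapply(pairs, function(pr) paste(pr[2], "vs", pr[1]), "")
  attr(out, "dispersion") <- phi
  out
}

## Signed fold change towards `level` and the matching adj_p, from the
## two tests of `tests` that involve `level`.
.towards <- function(tests, level) {
  sel <- vapply(tests, function(tt) {
    attr(tt, "groupA") == level || attr(tt, "groupB") == level
  }, logical(1))
  tt <- tests[sel]
  if (length(tt) != 2L)
    stop("missing comparison for group ", level, call. = FALSE)
  lapply(tt, function(x) {
    sgn <- if (attr(x, "groupB") == level) 1 else -1
    data.frame(gene_id = x$gene_id, fc = sgn * x$log2_fold_change,
               adj_p = x$adj_p, stringsAsFactors = FALSE)
  })
}

#' Classify genes by morph bias
#'
#' @param tests list of the three pairwise [nb_exact_test()] results
#'   among morphs (as produced by [pairwise_exact_tests()]).
#' @param params a [classification_params()].
#' @return data.frame (`gene_id`, `morph_bias`, `class`, `degree`):
#'   `morph_bias` is the winning morph or `"unbiased"`; `class` codes it
#'   as M/F/P/unbiased; `degree` is `"+"`, `"++"` or `"none"`.
#' @export
classify_morph_bias <- function(tests, params = classification_params()) {
  morphs <- unique(unlist(lapply(tests, function(x)
    c(attr(x, "groupA"), attr(x, "groupB")))))
  if (length(morphs) != 3L)
    stop("expected pairwise tests among exactly three morphs", call. = FALSE)
  gene_id <- tests[[1]]$gene_id
  bias <- rep("unbiased", length(gene_id))
  degree <- rep("none", length(gene_id))
  for (m in morphs) {
    tw <- .towards(tests, m)
    hit <- tw[[1]]$fc > params$lfc_biased & tw[[2]]$fc > params$lfc_biased &
      tw[[1]]$adj_p < params$alpha & tw[[2]]$adj_p < params$alpha
    lim <- hit & tw[[1]]$fc > params$lfc_limited & tw[[2]]$fc > params$lfc_limited
    bias[hit] <- m
    degree[hit] <- "+"
    degree[lim] <- "++"
  }
  cls <- c(male = "M", sexual_female = "F", parthenogenetic_female = "P",
           unbiased = "unbiased")[bias]
  cls[is.na(cls)] <- bias[is.na(cls)]  # non-standard morph names pass through
  data.frame(gene_id = gene_id, morph_bias = bias, class = unname(cls),
             degree = degree, stringsAsFactors = FALSE)
}

#' Classify genes by tissue bias within each morph
#'
#' Applies the dual-comparison rule of [classify_morph_bias()] to the
#' three tissues of one morph: a gene is tissue-biased in a morph when it
#' is significantly overexpressed in that tissue in both comparisons with
#' the other two tissues of the same morph.
#'
#' @param tissue_tests named list (one element per morph) of pairwise
#'   test lists among the three tissues of that morph.
#' @param params a [classification_params()].
#' @return data.frame with `gene_id` and one `tissue_bias_<morph>` column
#'   per morph (values: tissue name or `"none"`).
#' @export
classify_tissue_bias <- function(tissue_tests, params = classification_params()) {
  out <- NULL
  for (m in names(tissue_tests)) {
    tests <- tissue_tests[[m]]
    tissues <- unique(unlist(lapply(tests, function(x)
      c(attr(x, "groupA"), attr(x, "groupB")))))
    if (length(tissues) != 3L)
      stop("expected pairwise tests among exactly three tissues for morph ",
           m, call. = FALSE)
    gene_id <- tests[[1]]$gene_id
    lab <- rep("none", length(gene_id))
    for (t in tissues) {
      tw <- .towards(tests, t)
      hit <- tw[[1]]$fc > params$lfc_biased & tw[[2]]$fc > params$lfc_biased &
        tw[[1]]$adj_p < params$alpha & tw[[2]]$adj_p < params$alpha
      lab[hit] <- t
    }
    df <- data.frame(gene_id = gene_id, lab = lab, stringsAsFactors = FALSE)
    names(df)[2] <- paste0("tissue_bias_", m)
    out <- if (is.null(out)) df else merge(out, df, by = "gene_id",
                                           all = TRUE, sort = FALSE)
  }
  out
}

#' Attach chromosome class to a gene table
#'
#' @param genes character gene identifiers, or a data.frame with a
#'   `gene_id` column (returned with a `chromosome_class` column added).
#' @param annotation data.frame mapping `gene_id` to `chromosome`.
#' @param x_chromosomes chromosome names counted as X-linked.
#' @return `"X"`, `"autosome"` or `"unplaced"` per gene; genes absent from
#'   the annotation are labeled `"unplaced"` with a warning giving their
#'   count.
#' @export
annotate_chromosome <- function(genes, annotation, x_chromosomes = "X") {
  ids <- if (is.data.frame(genes)) genes$gene_id else genes
  chr <- annotation$chromosome[match(ids, annotation$gene_id)]
  n_missing <- sum(is.na(chr))
  if (n_missing > 0)
    warning(n_missing, " gene(s) absent from the annotation; labeled unplaced")
  cls <- ifelse(is.na(chr), "unplaced",
                ifelse(chr %in% x_chromosomes, "X", "autosome"))
  if (is.data.frame(genes)) {
    genes$chromosome_class <- cls
    genes
  } else cls
}

#' Full outgroup classification
#'
#' Convenience wrapper running the whole classification stage on the
#' outgroup datasets: TMM + CPM + expression filter (CPM > 1 in at least
#' `min_libraries`), pairwise exact tests among morphs on the whole-body
#' data, tissue tests within each morph on the tissue data, and
#' chromosome annotation.
#'
#' @param body list with `counts` and `metadata` (whole-body outgroup,
#'   metadata needs `sample_id` and `morph`).
#' @param tissue optional list with `counts` and `metadata` (tissue
#'   outgroup; metadata additionally needs `tissue`).
#' @param annotation optional data.frame (`gene_id`, `chromosome`).
#' @param params a [classification_params()].
#' @param min_libraries,min_libraries_tissue expression-filter thresholds
#'   for the two datasets.
#' @return an expression class table: `gene_id`, `morph_bias`, `class`,
#'   `degree`, per-morph `tissue_bias_*` columns, `tissue_bias` (tissue
#'   call in the gene's own biased morph) and `chromosome_class`.
#' @export
classify_outgroup <- function(body, tissue = NULL, annotation = NULL,
                              params = classification_params(),
                              min_libraries = 2L, min_libraries_tissue = 2L) {
  counts <- round(as.matrix(body$counts))
  f <- tmm_factors(counts)
  cpm_mat <- cpm(counts, f)
  keep <- filter_expressed(cpm_mat, 1, min_libraries)$keep
  counts <- counts[keep, , drop = FALSE]
  morphs <- body$metadata$morph[match(colnames(counts), body$metadata$sample_id)]
  tests <- pairwise_exact_tests(counts, morphs,
                                lib_size = colSums(counts) * f, params = params)
  tab <- classify_morph_bias(tests, params)

  if (!is.null(tissue)) {
    tcounts <- round(as.matrix(tissue$counts))
    tf <- tmm_factors(tcounts)
    tcpm <- cpm(tcounts, tf)
    tkeep <- filter_expressed(tcpm, 1, min_libraries_tissue)$keep
    tcounts <- tcounts[tkeep, , drop = FALSE]
    tmeta <- tissue$metadata[match(colnames(tcounts), tissue$metadata$sample_id), ]
    tsize <- (colSums(round(as.matrix(tissue$counts))) * tf)[colnames(tcounts)]
    per_morph <- lapply(setNames(unique(tmeta$morph), unique(tmeta$morph)),
      function(m) {
        sel <- tmeta$morph == m
        pairwise_exact_tests(tcounts[, sel, drop = FALSE], tmeta$tissue[sel],
                             lib_size = tsize[sel], params = params)
      })
    ttab <- classify_tissue_bias(per_morph, params)
    tab <- merge(tab, ttab, by = "gene_id", all.x = TRUE, sort = FALSE)
    tb_cols <- paste0("tissue_bias_", unique(tmeta$morph))
    for (cc in tb_cols) tab[[cc]][is.na(tab[[cc]])] <- "none"
    # tissue call in the gene's own biased morph (e.g. testis-biased =
    # gonad-biased in males for male-biased genes)
    own <- rep("none", nrow(tab))
    for (m in unique(tmeta$morph)) {
      sel <- tab$morph_bias == m
      own[sel] <- tab[[paste0("tissue_bias_", m)]][sel]
    }
    tab$tissue_bias <- own
  } else {
    tab$tissue_bias <- "none"
  }
  if (!is.null(annotation)) tab <- annotate_chromosome(tab, annotation)
  tab
}
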
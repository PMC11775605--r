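## Synthetic-data generators emulating the pea-aphid study design:
## 40 focal whole-body libraries (4 CP lineages x 3 morphs x 2 reps +
## 4 OP lineages x 2 morphs x 2 reps), a 6-library whole-body outgroup,
## an 18-library tissue outgroup, and biallelic SNP genotypes for the
## 8 focal lineages.

MORPHS <- c("male", "sexual_female", "parthenogenetic_female")
TISSUES <- c("head", "legs", "gonads")
CLASS_TO_MORPH <- c(M = "male", F = "sexual_female", P = "parthenogenetic_female")

#' Default injected OP-to-CP shifts
#'
#' One row per (morph, gene class) combination that receives a non-zero
#' log2 shift in OP samples; `tissue` restricts the shift to genes carrying
#' that tissue-bias call (NA = any). The defaults reproduce the headline
#' effects of the study system: sexual female-biased genes shifted by 0.13
#' in parthenogenetic females, parthenogenetic female-biased genes by 0.13
#' in males, and testis-biased male-biased genes by 0.85 in males.
#'
#' @return data.frame with columns `morph`, `class`, `tissue`, `delta`.
#' @export
default_shift_spec <- function() {
  data.frame(
    morph  = c("parthenogenetic_female", "male", "male"),
    class  = c("F", "P", "M"),
    tissue = c(NA, NA, "gonads"),
    delta  = c(0.13, 0.13, 0.85),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for RNA-seq count generation
#'
#' Defines the statistical structure the analysis assumes: a log-normal
#' baseline expression law, log-normal per-gene negative-binomial
#' dispersions, morph-bias effects for a configurable fraction of genes,
#' per-lineage random effects (shared across morphs of a lineage, as
#' lineages are clonal genotypes), and injected OP-to-CP log2 shifts.
#'
#' @param n_genes number of genes.
#' @param frac_class named fractions of genes per morph-bias class
#'   (`M`, `F`, `P`, `unbiased`); must sum to 1.
#' @param lfc_bias log2 effect size of morph-biased (`+`) genes.
#' @param lfc_limited_frac fraction of biased genes drawn as morph-limited
#'   (`++`), i.e. given `lfc_limited_value` instead of `lfc_bias`.
#' @param lfc_limited_value log2 effect size of morph-limited genes
#'   (must exceed 2 for the truth label to match the classification rule).
#' @param frac_tissue_biased fraction of morph-biased genes that also carry
#'   a tissue bias in their own morph.
#' @param tissue_probs named sampling probabilities over tissues for
#'   tissue-biased genes.
#' @param lfc_tissue log2 effect size of the tissue bias in the tissue
#'   outgroup dataset.
#' @param shift_spec data.frame of injected OP-to-CP shifts, see
#'   [default_shift_spec()].
#' @param dispersion_meanlog,dispersion_sdlog log-normal law of per-gene NB
#'   dispersions.
#' @param libsize_meanlog,libsize_sdlog log-normal law of library sizes.
#' @param n_lineages_per_mode focal lineages per reproductive mode.
#' @param n_replicates replicates per (lineage, morph).
#' @param lineage_sd SD (log2 scale) of the per-gene, per-lineage random
#'   expression effect.
#' @param frac_x_linked fraction of genes assigned to the X chromosome.
#' @param frac_silent fraction of genes drawn near-silent (to exercise the
#'   CPM filter).
#' @param baseline_meanlog2,baseline_sdlog2 normal law of baseline log2
#'   expression.
#' @param seed RNG seed; all generators are reproducible given the seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       frac_class = c(M = 0.10, F = 0.10, P = 0.05, unbiased = 0.75),
                       lfc_bias = 2,
                       lfc_limited_frac = 0.3,
                       lfc_limited_value = 3.2,
                       frac_tissue_biased = 0.5,
                       tissue_probs = c(head = 0.25, legs = 0.25, gonads = 0.5),
                       lfc_tissue = 2,
                       shift_spec = default_shift_spec(),
                       dispersion_meanlog = log(0.08),
                       dispersion_sdlog = 0.5,
                       libsize_meanlog = log(1e6),
                       libsize_sdlog = 0.15,
                       n_lineages_per_mode = 4,
                       n_replicates = 2,
                       lineage_sd = 0.15,
                       frac_x_linked = 0.3,
                       frac_silent = 0.2,
                       baseline_meanlog2 = 5.5,
                       baseline_sdlog2 = 2,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fc <- cfg$frac_class
  if (!all(c("M", "F", "P", "unbiased") %in% names(fc)))
    stop("frac_class must name classes M, F, P and unbiased", call. = FALSE)
  if (any(fc < 0) || any(fc > 1) || abs(sum(fc) - 1) > 1e-8)
    stop("frac_class values must lie in [0,1] and sum to 1", call. = FALSE)
  for (fr in c("lfc_limited_frac", "frac_tissue_biased", "frac_x_linked", "frac_silent"))
    if (cfg[[fr]] < 0 || cfg[[fr]] > 1)
      stop(sprintf("%s must lie in [0,1]", fr), call. = FALSE)
  for (ct in c("n_genes", "n_lineages_per_mode", "n_replicates"))
    if (cfg[[ct]] < 1) stop(sprintf("%s must be >= 1", ct), call. = FALSE)
  if (cfg$lineage_sd < 0) stop("lineage_sd must be >= 0", call. = FALSE)
  ss <- cfg$shift_spec
  if (!is.null(ss)) {
    if (!all(c("morph", "class", "delta") %in% names(ss)))
      stop("shift_spec needs columns morph, class, delta", call. = FALSE)
    if (!all(ss$morph %in% MORPHS)) stop("unknown morph in shift_spec", call. = FALSE)
    if (!all(ss$class %in% c("M", "F", "P", "unbiased")))
      stop("unknown class in shift_spec", call. = FALSE)
  }
  invisible(cfg)
}

## Gene-level ground truth shared by focal and outgroup generators.
## Consumes RNG from cfg$seed so both generators rebuild identical truth.
.sim_truth <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  cls <- sample(names(cfg$frac_class), n, replace = TRUE, prob = cfg$frac_class)
  biased <- cls != "unbiased"
  limited <- biased & runif(n) < cfg$lfc_limited_frac
  lfc <- ifelse(biased, ifelse(limited, cfg$lfc_limited_value, cfg$lfc_bias), 0)
  degree <- ifelse(!biased, "none", ifelse(lfc > 2, "++", "+"))
  tissue <- rep("none", n)
  tb <- biased & runif(n) < cfg$frac_tissue_biased
  tissue[tb] <- sample(names(cfg$tissue_probs), sum(tb), replace = TRUE,
                       prob = cfg$tissue_probs)
  chrom <- ifelse(runif(n) < cfg$frac_x_linked, "X",
                  sample(c("A1", "A2", "A3"), n, replace = TRUE))
  base <- rnorm(n, cfg$baseline_meanlog2, cfg$baseline_sdlog2)
  silent <- runif(n) < cfg$frac_silent
  base[silent] <- base[silent] - 7
  phi <- rlnorm(n, cfg$dispersion_meanlog, cfg$dispersion_sdlog)
  nlin <- 2L * cfg$n_lineages_per_mode
  lineage_ids <- c(paste0("CP", seq_len(cfg$n_lineages_per_mode)),
                   paste0("OP", seq_len(cfg$n_lineages_per_mode)))
  lin_eff <- matrix(rnorm(n * nlin, 0, cfg$lineage_sd), n, nlin,
                    dimnames = list(gene_id, lineage_ids))
  out_eff <- rnorm(n, 0, cfg$lineage_sd)
  list(
    table = data.frame(
      gene_id = gene_id, class = cls, degree = degree, lfc = lfc,
      tissue_bias = tissue, chromosome = chrom,
      chromosome_class = ifelse(chrom == "X", "X", "autosome"),
      baseline_log2 = base, dispersion = phi, silent = silent,
      stringsAsFactors = FALSE
    ),
    lineage_effect = lin_eff,
    outgroup_effect = out_eff,
    lineage_ids = lineage_ids
  )
}

## Injected delta (log2) per gene for an OP library of the given morph.
.delta_for <- function(truth_tab, shift_spec, morph) {
  d <- numeric(nrow(truth_tab))
  if (is.null(shift_spec) || nrow(shift_spec) == 0L) return(d)
  for (i in seq_len(nrow(shift_spec))) {
    row <- shift_spec[i, ]
    if (row$morph != morph) next
    hit <- truth_tab$class == row$class
    if (!is.na(row$tissue)) hit <- hit & truth_tab$tissue_bias == row$tissue
    d[hit] <- d[hit] + row$delta
  }
  d
}

## NB draw for one library. log2_mu: per-gene relative log2 expression.
.draw_library <- function(log2_mu, phi, libsize) {
  rel <- 2^log2_mu
  mu <- rel / sum(rel) * libsize
  rnbinom(length(mu), mu = mu, size = 1 / phi)
}

#' Simulate the 40-library focal dataset
#'
#' Counts are negative-binomial with mean
#' `baseline x 2^(morph effect) x 2^(lineage effect) x 2^(delta)` scaled to
#' the drawn library size, where `delta` is the injected OP-to-CP shift for
#' OP libraries of a target morph/class (see [default_shift_spec()]).
#' OP lineages produce males and parthenogenetic females only; CP lineages
#' produce all three morphs.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (gene x sample integer matrix), `metadata`
#'   (one row per library: sample_id, lineage, mode, morph, replicate,
#'   tissue, dataset) and `truth` (per-gene class labels, effects and
#'   injected shifts).
#' @export
simulate_counts <- function(cfg) {
  validate_sim_config(cfg)
  tr <- .sim_truth(cfg)
  tab <- tr$table
  set.seed(cfg$seed + 1L)
  meta <- do.call(rbind, lapply(tr$lineage_ids, function(lin) {
    mode <- substr(lin, 1, 2)
    morphs <- if (mode == "CP") MORPHS else c("male", "parthenogenetic_female")
    expand.grid(lineage = lin, mode = mode, morph = morphs,
                replicate = seq_len(cfg$n_replicates),
                stringsAsFactors = FALSE)
  }))
  meta$tissue <- "whole_body"
  meta$dataset <- "focal"
  meta$sample_id <- sprintf("%s_%s_r%d", meta$lineage, meta$morph, meta$replicate)
  libsizes <- rlnorm(nrow(meta), cfg$libsize_meanlog, cfg$libsize_sdlog)
  counts <- matrix(0L, cfg$n_genes, nrow(meta),
                   dimnames = list(tab$gene_id, meta$sample_id))
  morph_of_class <- CLASS_TO_MORPH[tab$class]
  deltas <- lapply(setNames(MORPHS, MORPHS),
                   function(m) .delta_for(tab, cfg$shift_spec, m))
  for (j in seq_len(nrow(meta))) {
    m <- meta$morph[j]
    log2_mu <- tab$baseline_log2 +
      ifelse(!is.na(morph_of_class) & morph_of_class == m, tab$lfc, 0) +
      tr$lineage_effect[, meta$lineage[j]]
    if (meta$mode[j] == "OP") log2_mu <- log2_mu + deltas[[m]]
    counts[, j] <- .draw_library(log2_mu, tab$dispersion, libsizes[j])
  }
  tab$delta_male <- deltas$male
  tab$delta_parthenogenetic_female <- deltas$parthenogenetic_female
  list(counts = counts, metadata = meta[, c("sample_id", "lineage", "mode",
       "morph", "replicate", "tissue", "dataset")], truth = tab)
}

#' Simulate the outgroup datasets
#'
#' Generates the 6-library whole-body outgroup (3 morphs x 2 replicates)
#' and the 18-library tissue outgroup (3 morphs x 3 tissues x 2
#' replicates), sharing the gene set and true morph-bias effects with
#' [simulate_counts()] so that classes learned on the outgroup transfer to
#' the focal data. Tissue-biased genes are overexpressed by `lfc_tissue`
#' in their target tissue within their own morph.
#'
#' @param cfg a [sim_config()]; must be the same object passed to
#'   [simulate_counts()] for the gene sets to match.
#' @return list with `body` (counts + metadata), `tissue` (counts +
#'   metadata) and `truth`.
#' @export
simulate_outgroup <- function(cfg) {
  validate_sim_config(cfg)
  tr <- .sim_truth(cfg)
  tab <- tr$table
  set.seed(cfg$seed + 2L)
  morph_of_class <- CLASS_TO_MORPH[tab$class]

  body_meta <- expand.grid(morph = MORPHS, replicate = seq_len(cfg$n_replicates),
                           stringsAsFactors = FALSE)
  body_meta$lineage <- "OG"
  body_meta$mode <- "outgroup"
  body_meta$tissue <- "whole_body"
  body_meta$dataset <- "outgroup_body"
  body_meta$sample_id <- sprintf("OG_%s_r%d", body_meta$morph, body_meta$replicate)
  libsizes <- rlnorm(nrow(body_meta), cfg$libsize_meanlog, cfg$libsize_sdlog)
  body_counts <- matrix(0L, cfg$n_genes, nrow(body_meta),
                        dimnames = list(tab$gene_id, body_meta$sample_id))
  for (j in seq_len(nrow(body_meta))) {
    m <- body_meta$morph[j]
    log2_mu <- tab$baseline_log2 +
      ifelse(!is.na(morph_of_class) & morph_of_class == m, tab$lfc, 0) +
      tr$outgroup_effect
    body_counts[, j] <- .draw_library(log2_mu, tab$dispersion, libsizes[j])
  }

  tis_meta <- expand.grid(morph = MORPHS, tissue = TISSUES,
                          replicate = seq_len(cfg$n_replicates),
                          stringsAsFactors = FALSE)
  tis_meta$lineage <- "OG"
  tis_meta$mode <- "outgroup"
  tis_meta$dataset <- "outgroup_tissue"
  tis_meta$sample_id <- sprintf("OG_%s_%s_r%d", tis_meta$morph, tis_meta$tissue,
                                tis_meta$replicate)
  libsizes <- rlnorm(nrow(tis_meta), cfg$libsize_meanlog, cfg$libsize_sdlog)
  tis_counts <- matrix(0L, cfg$n_genes, nrow(tis_meta),
                       dimnames = list(tab$gene_id, tis_meta$sample_id))
  for (j in seq_len(nrow(tis_meta))) {
    m <- tis_meta$morph[j]
    t <- tis_meta$tissue[j]
    log2_mu <- tab$baseline_log2 +
      ifelse(!is.na(morph_of_class) & morph_of_class == m, tab$lfc, 0) +
      ifelse(!is.na(morph_of_class) & morph_of_class == m &
               tab$tissue_bias == t, cfg$lfc_tissue, 0) +
      tr$outgroup_effect
    tis_counts[, j] <- .draw_library(log2_mu, tab$dispersion, libsizes[j])
  }
  cols <- c("sample_id", "lineage", "mode", "morph", "replicate", "tissue", "dataset")
  list(body = list(counts = body_counts, metadata = body_meta[, cols]),
       tissue = list(counts = tis_counts, metadata = tis_meta[, cols]),
       truth = tab)
}

#' Genotype simulation configuration
#'
#' Allele frequencies drift from a shared ancestral frequency first to a
#' per-mode frequency (SD `divergence_between_mode`) and then to a
#' per-lineage frequency (SD `divergence_within_mode`), clamped to
#' \[0, 1\]. Genotypes are diploid dosages drawn from the lineage
#' frequency with common random numbers across lineages, so zero drift
#' yields identical genotypes and hence zero Nei distance. The between-mode
#' component is shared by all lineages of a mode, so modes separate on the
#' NJ tree and PCA even when the independent within-mode component is of
#' comparable magnitude; the defaults put within-mode Nei distances near
#' 0.15, the scale observed in the real lineage panel.
#'
#' @param n_snps number of biallelic SNPs.
#' @param divergence_within_mode,divergence_between_mode drift SDs.
#' @param depth_mean,depth_size negative-binomial law of per-genotype depth.
#' @param gq_mean,gq_sd normal law of per-genotype quality (rounded,
#'   clamped to \[0, 99\]).
#' @param n_lineages_per_mode lineages per reproductive mode.
#' @param seed RNG seed.
#' @return list of class `genotype_sim_config`.
#' @export
genotype_sim_config <- function(n_snps = 11449,
                                divergence_within_mode = 0.2,
                                divergence_between_mode = 0.15,
                                depth_mean = 200, depth_size = 20,
                                gq_mean = 60, gq_sd = 15,
                                n_lineages_per_mode = 4,
                                seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_snps < 1) stop("n_snps must be >= 1", call. = FALSE)
  if (cfg$divergence_within_mode < 0 || cfg$divergence_between_mode < 0)
    stop("divergence parameters must be >= 0", call. = FALSE)
  if (cfg$depth_mean <= 0 || cfg$depth_size <= 0)
    stop("depth law parameters must be > 0", call. = FALSE)
  class(cfg) <- "genotype_sim_config"
  cfg
}

#' Simulate biallelic SNP genotypes for the focal lineages
#'
#' @param cfg a [genotype_sim_config()].
#' @return list with `genotype` (SNP x lineage alt-allele dosage in
#'   0/1/2), `dp` and `gq` matrices, `lineage_ids`, `modes`, `snp_ids`,
#'   `chrom`/`pos` and the config.
#' @export
simulate_genotypes <- function(cfg) {
  if (!inherits(cfg, "genotype_sim_config"))
    stop("cfg must come from genotype_sim_config()", call. = FALSE)
  set.seed(cfg$seed)
  nlin <- 2L * cfg$n_lineages_per_mode
  lineage_ids <- c(paste0("CP", seq_len(cfg$n_lineages_per_mode)),
                   paste0("OP", seq_len(cfg$n_lineages_per_mode)))
  modes <- substr(lineage_ids, 1, 2)
  n <- cfg$n_snps
  p0 <- runif(n, 0.1, 0.9)
  p_mode <- cbind(CP = pmin(pmax(p0 + rnorm(n, 0, cfg$divergence_between_mode), 0), 1),
                  OP = pmin(pmax(p0 + rnorm(n, 0, cfg$divergence_between_mode), 0), 1))
  u <- runif(n)  # common random numbers: zero drift => identical genotypes
  geno <- matrix(0L, n, nlin, dimnames = list(sprintf("snp%05d", seq_len(n)),
                                              lineage_ids))
  for (j in seq_len(nlin)) {
    p_l <- pmin(pmax(p_mode[, modes[j]] +
                       rnorm(n, 0, cfg$divergence_within_mode), 0), 1)
    geno[, j] <- qbinom(u, 2L, p_l)
  }
  dp <- matrix(rnbinom(n * nlin, mu = cfg$depth_mean, size = cfg$depth_size),
               n, nlin, dimnames = dimnames(geno))
  gq <- matrix(pmin(pmax(round(rnorm(n * nlin, cfg$gq_mean, cfg$gq_sd)), 0L), 99L),
               n, nlin, dimnames = dimnames(geno))
  list(genotype = geno, dp = dp, gq = gq,
       lineage_ids = lineage_ids, modes = modes,
       snp_ids = rownames(geno),
       chrom = rep("A1", n), pos = seq_len(n) * 100L,
       config = cfg)
}
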
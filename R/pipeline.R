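## End-to-end orchestration: simulate (optional) -> normalize/filter ->
## classify on the outgroup -> shift tests and robustness checks ->
## genetic and transcriptomic divergence. All randomness derives from the
## single config seed; reruns with the same config are identical.

#' Pipeline configuration
#'
#' In simulation mode (the default) the focal, outgroup and genotype
#' data are generated from `sim` and `geno_sim`; otherwise paths to
#' counts/metadata/annotation TSVs and a VCF may be supplied.
#'
#' @param seed global seed; recorded in every output.
#' @param sim a [sim_config()] (its `seed` field is overridden by `seed`).
#' @param geno_sim a [genotype_sim_config()] (seed overridden by
#'   `seed + 1`).
#' @param counts_file,metadata_file,annotation_file,vcf_file optional
#'   input paths (used when `simulate = FALSE`).
#' @param outgroup_body_counts_file,outgroup_body_metadata_file,
#'   outgroup_tissue_counts_file,outgroup_tissue_metadata_file optional
#'   outgroup input paths.
#' @param simulate generate inputs from the simulation configs.
#' @param min_libraries_focal CPM-filter threshold for the focal data
#'   (8 of the 40 libraries).
#' @param class_params a [classification_params()].
#' @param shift a [shift_params()].
#' @param filter_params a [variant_filter_params()].
#' @param n_boot NJ bootstrap replicates.
#' @param n_perm Mantel permutations.
#' @param run_loo,run_pairwise run the leave-one-out and pairwise-lineage
#'   robustness checks.
#' @param transcriptomic_standardize per-gene standardization for
#'   transcriptomic distances (`"zscore"` or `"center"`).
#' @param outdir optional output directory; results are written as
#'   TSV/JSON/Newick when set.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            geno_sim = genotype_sim_config(seed = seed + 1L),
                            counts_file = NULL, metadata_file = NULL,
                            annotation_file = NULL, vcf_file = NULL,
                            outgroup_body_counts_file = NULL,
                            outgroup_body_metadata_file = NULL,
                            outgroup_tissue_counts_file = NULL,
                            outgroup_tissue_metadata_file = NULL,
                            simulate = TRUE,
                            min_libraries_focal = 8L,
                            class_params = classification_params(),
                            shift = shift_params(),
                            filter_params = variant_filter_params(),
                            n_boot = 1000L, n_perm = 999L,
                            run_loo = TRUE, run_pairwise = TRUE,
                            transcriptomic_standardize = "zscore",
                            outdir = NULL) {
  cfg <- as.list(environment())
  cfg$sim$seed <- seed
  cfg$geno_sim$seed <- seed + 1L
  if (!simulate) {
    needed <- c("counts_file", "metadata_file")
    for (nm in needed) if (is.null(cfg[[nm]]))
      stop(nm, " is required when simulate = FALSE", call. = FALSE)
    for (nm in grep("_file$", names(cfg), value = TRUE)) {
      if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]]))
        stop("input file does not exist: ", cfg[[nm]], call. = FALSE)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

## Rolling polynomial hash of the serialized config, for output provenance.
.config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 69069 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> TMM/CPM/filter -> outgroup
#' classification -> OP-to-CP shift tests, subdivisions and robustness
#' checks -> SNP filtering, Nei distances, NJ tree with bootstrap, PCA,
#' transcriptomic distances, Mantel tests and mode-divergence
#' comparisons. When `config$outdir` is set, all tables are written as
#' TSV/JSON/Newick together with a manifest recording the seed and a
#' config hash.
#'
#' @param config a [pipeline_config()].
#' @return a result bundle (list); see [render_report()] for the summary
#'   tables.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  ## -- data ------------------------------------------------------------
  dat <- stage("data", {
    if (config$simulate) {
      foc <- simulate_counts(config$sim)
      og <- simulate_outgroup(config$sim)
      geno <- simulate_genotypes(config$geno_sim)
      annotation <- foc$truth[, c("gene_id", "chromosome")]
      list(counts = foc$counts, meta = foc$metadata, truth = foc$truth,
           outgroup = og, geno = geno, annotation = annotation)
    } else {
      counts <- read_counts_tsv(config$counts_file)
      meta <- read_metadata_tsv(config$metadata_file)
      annotation <- if (!is.null(config$annotation_file))
        read_metadata_tsv(config$annotation_file) else NULL
      og <- NULL
      if (!is.null(config$outgroup_body_counts_file)) {
        og <- list(body = list(
          counts = read_counts_tsv(config$outgroup_body_counts_file),
          metadata = read_metadata_tsv(config$outgroup_body_metadata_file)))
        if (!is.null(config$outgroup_tissue_counts_file))
          og$tissue <- list(
            counts = read_counts_tsv(config$outgroup_tissue_counts_file),
            metadata = read_metadata_tsv(config$outgroup_tissue_metadata_file))
      }
      geno <- if (!is.null(config$vcf_file))
        read_genotypes_vcf(config$vcf_file) else NULL
      list(counts = counts, meta = meta, truth = NULL, outgroup = og,
           geno = geno, annotation = annotation)
    }
  })

  ## -- normalization ---------------------------------------------------
  norm <- stage("normalization", {
    f <- tmm_factors(round(dat$counts))
    cpm_all <- cpm(dat$counts, f)
    filt <- filter_expressed(cpm_all, 1, config$min_libraries_focal)
    cpm_f <- cpm_all[filt$keep, , drop = FALSE]
    avg <- average_two_stage(cpm_f, dat$meta)
    list(factors = f, cpm = cpm_f, n_retained = filt$n_retained, avg = avg)
  })

  ## -- classification --------------------------------------------------
  class_table <- if (!is.null(dat$outgroup)) stage("classification", {
    classify_outgroup(dat$outgroup$body, dat$outgroup$tissue,
                      annotation = dat$annotation,
                      params = config$class_params)
  }) else NULL

  ## -- shift analysis --------------------------------------------------
  shift_res <- if (!is.null(class_table)) stage("shift", {
    per_morph <- lapply(setNames(config$shift$morphs, config$shift$morphs),
      function(m) {
        st <- shift_table(norm$avg$mode, m, class_table, config$shift)
        subs <- list(degree = subdivide_and_test(st, "degree"))
        if ("chromosome_class" %in% names(st))
          subs$chromosome_class <- subdivide_and_test(st, "chromosome_class")
        if ("tissue_bias" %in% names(st))
          subs$tissue_bias <- subdivide_and_test(st, "tissue_bias")
        pw <- if (config$run_pairwise)
          pairwise_lineage_ratios(norm$avg$lineage, m, class_table,
                                  config$shift) else NULL
        list(table = st, class_tests = class_shift_tests(st),
             subdivisions = subs, pairwise = pw)
      })
    loo <- if (config$run_loo)
      leave_one_out_check(dat$counts, dat$meta, config$class_params,
                          config$shift) else NULL
    list(per_morph = per_morph, leave_one_out = loo)
  }) else NULL

  ## -- genetic distances -----------------------------------------------
  genet <- if (!is.null(dat$geno)) stage("genetics", {
    fv <- filter_variants(dat$geno, config$filter_params)
    nei <- nei_distance(fv$genotype)
    boot <- bootstrap_support(fv$genotype, n_boot = config$n_boot,
                              seed = config$seed + 2L)
    modes <- setNames(substr(colnames(fv$genotype), 1, 2),
                      colnames(fv$genotype))
    split_support <- bipartition_support(
      boot, names(modes)[modes == "OP"])
    pca <- genotype_pca(fv$genotype)
    div <- focal_mode_divergence(nei, modes)
    list(filtered = fv, nei = nei, tree = boot$tree, boot = boot,
         mode_split_support = split_support, pca = pca, modes = modes,
         divergence = div)
  }) else NULL

  ## -- transcriptomic divergence ---------------------------------------
  trans <- if (!is.null(genet)) stage("transcriptomic", {
    modes <- genet$modes
    out <- lapply(setNames(config$shift$morphs, config$shift$morphs),
      function(m) {
        cols <- paste0(names(modes), ".", m)
        cols <- cols[cols %in% colnames(norm$avg$lineage)]
        expr <- norm$avg$lineage[, cols, drop = FALSE]
        colnames(expr) <- sub(paste0("\\.", m, "$"), "", cols)
        td <- transcriptomic_distance(expr, config$transcriptomic_standardize)
        mt <- mantel_test(genet$nei[colnames(expr), colnames(expr)], td,
                          n_perm = config$n_perm, seed = config$seed + 3L)
        list(dist = td,
             mantel = mt,
             divergence = focal_mode_divergence(td, modes),
             corrected = focal_mode_divergence(td, modes,
                                               correct_by = genet$nei))
      })
    out
  }) else NULL

  bundle <- list(config = config, seed = config$seed,
                 config_hash = .config_hash(config),
                 data = dat, normalization = norm,
                 class_table = class_table, shift = shift_res,
                 genetics = genet, transcriptomics = trans)
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

#' Summary tables from a result bundle
#'
#' Produces the per-class median/n/p tables (class x degree x chromosome
#' x tissue panels) and the mode-divergence comparison table. Missing
#' stages yield a `notes` entry rather than an error.
#'
#' @param bundle result of [run_pipeline()].
#' @return list with `shift_tables` (one data.frame per morph),
#'   `distance_table` and `notes`.
#' @export
render_report <- function(bundle) {
  notes <- character(0)
  shift_tables <- NULL
  if (!is.null(bundle$shift)) {
    shift_tables <- lapply(bundle$shift$per_morph, function(sm) {
      base <- sm$class_tests
      base$level <- "all"
      base$subdivision <- "class"
      rows <- base[, c("class", "subdivision", "level", "n_genes", "median",
                       "statistic", "p_value")]
      for (nm in names(sm$subdivisions)) {
        sd_ <- sm$subdivisions[[nm]]
        if (is.null(sd_)) { notes <<- c(notes, paste("empty panel:", nm)); next }
        sd_$subdivision <- nm
        rows <- rbind(rows, sd_[, c("class", "subdivision", "level", "n_genes",
                                    "median", "statistic", "p_value")])
      }
      rows
    })
  } else notes <- c(notes, "shift stage missing")

  distance_table <- NULL
  if (!is.null(bundle$genetics)) {
    g <- bundle$genetics$divergence
    rows <- data.frame(measure = "genetic",
                       mean_CP = g$mode_means[["CP"]],
                       mean_OP = g$mode_means[["OP"]],
                       p_value = g$p_value, stringsAsFactors = FALSE)
    if (!is.null(bundle$transcriptomics)) {
      for (m in names(bundle$transcriptomics)) {
        tr <- bundle$transcriptomics[[m]]
        rows <- rbind(rows,
          data.frame(measure = paste0("transcriptomic_", m),
                     mean_CP = tr$divergence$mode_means[["CP"]],
                     mean_OP = tr$divergence$mode_means[["OP"]],
                     p_value = tr$divergence$p_value),
          data.frame(measure = paste0("corrected_", m),
                     mean_CP = tr$corrected$mode_means[["CP"]],
                     mean_OP = tr$corrected$mode_means[["OP"]],
                     p_value = tr$corrected$p_value))
      }
    }
    distance_table <- rows
  } else notes <- c(notes, "genetics stage missing")

  list(shift_tables = shift_tables, distance_table = distance_table,
       notes = notes)
}

#' Write a result bundle to disk
#'
#' @param bundle result of [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(name) { files <<- c(files, name); file.path(outdir, name) }

  write_counts_tsv(bundle$normalization$cpm, put("cpm.tsv"))
  write_metadata_tsv(bundle$data$meta, put("metadata.tsv"))
  jsonlite::write_json(
    list(seed = bundle$seed, config_hash = bundle$config_hash,
         norm_factors = as.list(round(bundle$normalization$factors, 6)),
         n_retained = bundle$normalization$n_retained),
    put("normalization.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$class_table))
    write_metadata_tsv(bundle$class_table, put("class_table.tsv"))
  if (!is.null(bundle$shift)) {
    for (m in names(bundle$shift$per_morph)) {
      sm <- bundle$shift$per_morph[[m]]
      write_metadata_tsv(sm$table, put(paste0("shift_", m, ".tsv")))
      if (!is.null(sm$pairwise))
        write_metadata_tsv(sm$pairwise, put(paste0("pairwise_", m, ".tsv")))
    }
    if (!is.null(bundle$shift$leave_one_out))
      write_metadata_tsv(bundle$shift$leave_one_out, put("leave_one_out.tsv"))
  }
  rep_ <- render_report(bundle)
  if (!is.null(rep_$shift_tables))
    for (m in names(rep_$shift_tables))
      write_metadata_tsv(rep_$shift_tables[[m]],
                         put(paste0("class_tests_", m, ".tsv")))
  if (!is.null(rep_$distance_table))
    write_metadata_tsv(rep_$distance_table, put("distance_table.tsv"))
  if (!is.null(bundle$genetics)) {
    write_counts_tsv(bundle$genetics$nei, put("nei_distances.tsv"))
    ape::write.tree(bundle$genetics$tree, put("nj_tree.nwk"))
    write_counts_tsv(bundle$genetics$pca$coordinates, put("pca_coordinates.tsv"))
  }
  if (!is.null(bundle$transcriptomics))
    for (m in names(bundle$transcriptomics))
      write_counts_tsv(bundle$transcriptomics[[m]]$dist,
                       put(paste0("transcriptomic_dist_", m, ".tsv")))
  manifest <- list(seed = bundle$seed, config_hash = bundle$config_hash,
                   files = files,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of the YAML override the defaults of
#' [pipeline_config()]; nested blocks `sim`, `geno_sim`, `class_params`,
#' `shift` and `filter_params` override the corresponding constructor
#' defaults.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$seed)) args$seed <- as.integer(y$seed)
  seed <- if (is.null(args$seed)) 1L else args$seed
  if (!is.null(y$sim)) args$sim <- do.call(sim_config,
    utils::modifyList(list(seed = seed), y$sim))
  if (!is.null(y$geno_sim)) args$geno_sim <- do.call(genotype_sim_config,
    utils::modifyList(list(seed = seed + 1L), y$geno_sim))
  if (!is.null(y$class_params))
    args$class_params <- do.call(classification_params, y$class_params)
  if (!is.null(y$shift)) args$shift <- do.call(shift_params, y$shift)
  if (!is.null(y$filter_params))
    args$filter_params <- do.call(variant_filter_params, y$filter_params)
  for (nm in c("counts_file", "metadata_file", "annotation_file", "vcf_file",
               "simulate", "min_libraries_focal", "n_boot", "n_perm",
               "run_loo", "run_pairwise", "transcriptomic_standardize",
               "outdir"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(pipeline_config, args)
}
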
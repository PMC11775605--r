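## Plain-text interchange: counts/metadata/class tables as TSV, genotypes
## as minimal VCF (GT:DP:GQ), trees as Newick.

#' Write a gene x sample matrix as TSV
#'
#' First column `gene_id`, then one column per sample.
#'
#' @param mat matrix with gene rownames.
#' @param path output file.
#' @export
write_counts_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a gene x sample TSV written by [write_counts_tsv()]
#'
#' @param path input file.
#' @return numeric matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write sample metadata (or any data.frame) as TSV
#' @param df data.frame.
#' @param path output file.
#' @export
write_metadata_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TSV into a data.frame
#' @param path input file.
#' @return data.frame.
#' @export
read_metadata_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Write simulated genotypes as a minimal VCF (GT:DP:GQ)
#'
#' @param geno list from [simulate_genotypes()].
#' @param path output file (uncompressed `.vcf`).
#' @export
write_genotypes_vcf <- function(geno, path) {
  n <- nrow(geno$genotype)
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=morphshift simulate_genotypes (synthetic)",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(geno$genotype)), collapse = "\t")
  )
  body <- vapply(seq_len(n), function(i) {
    fields <- paste(gt_code[geno$genotype[i, ] + 1L], geno$dp[i, ],
                    geno$gq[i, ], sep = ":")
    paste(c(geno$chrom[i], geno$pos[i], geno$snp_ids[i], "A", "G", ".",
            "PASS", ".", "GT:DP:GQ", fields), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Keeps biallelic SNP records only (single-base REF and single ALT
#' allele); multi-allelic records and indels are excluded.
#'
#' @param path VCF file (plain or gzipped; read with vcfR).
#' @return list with `genotype` (alt-allele dosage, NA for missing),
#'   `dp`, `gq`, `snp_ids` and `lineage_ids`.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  bases <- c("A", "C", "G", "T")
  keep <- fix[, "REF"] %in% bases & fix[, "ALT"] %in% bases
  v <- v[keep, ]
  fix <- fix[keep, , drop = FALSE]
  gt <- vcfR::extract.gt(v, "GT")
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, "GQ", as.numeric = TRUE)
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  valid <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  dos[valid] <- (a1 == "1")[valid] + (a2 == "1")[valid]
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[
    is.na(ids) | ids == "."]
  rownames(dos) <- rownames(dp) <- rownames(gq) <- ids
  list(genotype = dos, dp = dp, gq = gq, snp_ids = ids,
       lineage_ids = colnames(dos))
}
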
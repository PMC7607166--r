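# File formats: strict TSV readers/writers and a minimal biallelic VCF 4.2
# subset. TSV dialect: tab-separated, UTF-8, '.' for missing, no quoting.
# Floats are written at 6 significant digits; VCF positions stay 1-based.

fmt_num <- function(x) formatC(x, format = "g", digits = 6)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = ".")
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects unique gene ids in column 1 and unique sample ids in the header;
#' every cell must be a non-negative integer.
#'
#' @param path Path to a tab-separated file.
#' @return Integer gene x sample matrix.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2) stopf("count file needs a gene id column plus samples")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) stopf("duplicate gene ids in %s", path)
  if (anyDuplicated(names(df)[-1])) stopf("duplicate sample ids in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) stopf("non-numeric or missing count cells")
  if (any(m < 0)) stopf("negative counts in %s", path)
  if (any(m != round(m))) stopf("non-integer counts in %s", path)
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write a count matrix to TSV
#' @param counts Integer gene x sample matrix.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Columns: `sample_id`, `race`, `cancer_type`, `time` (non-negative),
#' `event` (0/1).
#' @param path Path to a tab-separated file.
#' @return Clinical data frame.
#' @export
read_clinical <- function(path) {
  df <- read_tsv(path)
  need <- c("sample_id", "race", "cancer_type", "time", "event")
  if (!all(need %in% names(df)))
    stopf("clinical table needs columns %s", paste(need, collapse = ", "))
  df <- df[need]
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample ids")
  if (any(!is.finite(df$time)) || any(df$time < 0))
    stopf("`time` must be non-negative")
  if (!all(df$event %in% c(0L, 1L))) stopf("`event` must be 0 or 1")
  df$event <- as.integer(df$event)
  df
}

#' Write a clinical table to TSV
#' @param clinical Clinical data frame.
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  cl <- clinical
  cl$time <- fmt_num(cl$time)
  write_tsv(cl, path)
  invisible(path)
}

#' Read an allele-frequency table from TSV
#'
#' Columns: `snp_id`, `population`, `alt_freq` (alternate-allele frequency in
#' [0, 1]); one row per (SNP, population), every SNP present for all
#' populations. Effect-allele frequencies are always derived at use time from
#' the stored alternate-allele frequency, never stored.
#' @param path Path to a tab-separated file.
#' @return Allele-frequency data frame.
#' @export
read_freq_table <- function(path) {
  df <- read_tsv(path)
  validate_freq_table(df)
  df[c("snp_id", "population", "alt_freq")]
}

#' Write an allele-frequency table to TSV
#' @param freqs Allele-frequency data frame.
#' @param path Output path.
#' @export
write_freq_table <- function(freqs, path) {
  f <- freqs
  f$alt_freq <- fmt_num(f$alt_freq)
  write_tsv(f, path)
  invisible(path)
}

#' Read an eQTL association table from TSV
#'
#' Columns: `snp_id`, `gene_id`, `ref`, `alt`, `slope` (change in log2
#' expression per alternate-allele copy), `p`. Alleles must be single bases
#' A/C/G/T and p-values must lie in (0, 1]. The expression-increasing allele
#' is derived from the slope sign: alt if positive, ref if negative,
#' undetermined if zero.
#' @param path Path to a tab-separated file.
#' @return Data frame of eQTL records with an `increasing_allele` column.
#' @export
read_eqtl_table <- function(path) {
  df <- read_tsv(path)
  need <- c("snp_id", "gene_id", "ref", "alt", "slope", "p")
  if (nrow(df) == 0)
    return(data.frame(snp_id = character(), gene_id = character(),
                      ref = character(), alt = character(), slope = numeric(),
                      p = numeric(), increasing_allele = character(),
                      stringsAsFactors = FALSE))
  if (!all(need %in% names(df)))
    stopf("eQTL table needs columns %s", paste(need, collapse = ", "))
  df <- df[intersect(c(need, "padj"), names(df))]
  if (!all(df$ref %in% c("A", "C", "G", "T")) ||
      !all(df$alt %in% c("A", "C", "G", "T")))
    stopf("eQTL alleles must be single bases A, C, G or T")
  if (any(!is.finite(df$p)) || any(df$p <= 0) || any(df$p > 1))
    stopf("eQTL p-values must lie in (0, 1]")
  df$increasing_allele <- ifelse(df$slope > 0, "alt",
                                 ifelse(df$slope < 0, "ref", "undetermined"))
  df
}

#' Write an eQTL table to TSV
#' @param eqtls Data frame of eQTL records.
#' @param path Output path.
#' @export
write_eqtl_table <- function(eqtls, path) {
  e <- eqtls
  for (col in intersect(c("slope", "p", "padj"), names(e)))
    e[[col]] <- fmt_num(e[[col]])
  write_tsv(e, path)
  invisible(path)
}

#' Read genotype dosages from a minimal VCF
#'
#' Parses a biallelic-SNP VCF (4.2 subset: CHROM, POS, ID, REF, ALT, GT per
#' sample). Dosage is the count of alternate alleles in the GT field; missing
#' genotypes (`./.`) become `NA` and are excluded pairwise from downstream
#' eQTL fitting. Multi-allelic records are rejected: the downstream
#' consistency calculus is biallelic and a clear error beats silent
#' mishandling.
#'
#' @param path Path to an uncompressed VCF file.
#' @return A `genotype_matrix` (see [simulate_genotypes()]); its `populations`
#'   field is `NULL` until samples are matched to a clinical table.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-record VCFs drop to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt)))
    stopf("multi-allelic VCF records are not supported; split or drop them")
  ids <- fix[, "ID"]
  if (anyDuplicated(ids)) stopf("duplicate SNP ids in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  dosage <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  })
  rownames(dosage) <- ids
  structure(list(
    dosage = dosage,
    ref = setNames(fix[, "REF"], ids),
    alt = setNames(alt, ids),
    chrom = setNames(fix[, "CHROM"], ids),
    pos = setNames(as.integer(fix[, "POS"]), ids),
    populations = NULL
  ), class = "genotype_matrix")
}

#' Write a genotype matrix as a minimal VCF 4.2
#' @param genotypes A `genotype_matrix`.
#' @param path Output path.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  d <- genotypes$dosage
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(d)), collapse = "\t"))
  body <- vapply(seq_len(nrow(d)), function(i) {
    snp <- rownames(d)[i]
    gts <- ifelse(is.na(d[i, ]), "./.", gt_code[as.character(d[i, ])])
    paste(c(genotypes$chrom[[snp]], genotypes$pos[[snp]], snp,
            genotypes$ref[[snp]], genotypes$alt[[snp]], ".", "PASS", ".",
            "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write a full synthetic dataset to a directory
#'
#' Writes counts, clinical, allele-frequency and truth TSVs plus a minimal
#' VCF, the on-disk bundle the pipeline can re-read.
#' @param dataset A `disparity_dataset` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    genotypes = file.path(dir, "genotypes.vcf"),
    freqs = file.path(dir, "allele_freqs.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_counts(dataset$counts, paths[["counts"]])
  write_clinical(dataset$clinical, paths[["clinical"]])
  write_genotypes_vcf(dataset$genotypes, paths[["genotypes"]])
  write_freq_table(dataset$freqs, paths[["freqs"]])
  write_tsv(dataset$truth, paths[["truth"]])
  paths
}

#' Read a dataset bundle from a directory
#'
#' Counterpart of [write_dataset()]; genotype and frequency files are
#' optional. Sample ids must agree across the components present.
#' @param dir Directory holding `counts.tsv`, `clinical.tsv` and optionally
#'   `genotypes.vcf`, `allele_freqs.tsv`.
#' @return A `disparity_dataset`.
#' @export
read_dataset <- function(dir) {
  counts <- read_counts(file.path(dir, "counts.tsv"))
  clinical <- read_clinical(file.path(dir, "clinical.tsv"))
  if (!setequal(colnames(counts), clinical$sample_id))
    stopf("sample ids differ between counts and clinical table")
  counts <- counts[, clinical$sample_id, drop = FALSE]
  attr(counts, "populations") <- setNames(clinical$race, clinical$sample_id)
  genotypes <- NULL
  vcf <- file.path(dir, "genotypes.vcf")
  if (file.exists(vcf)) {
    genotypes <- read_genotypes_vcf(vcf)
    if (!all(clinical$sample_id %in% colnames(genotypes$dosage)))
      stopf("clinical samples missing from genotype VCF")
    genotypes$dosage <- genotypes$dosage[, clinical$sample_id, drop = FALSE]
    genotypes$populations <- setNames(clinical$race, clinical$sample_id)
  }
  freqs <- NULL
  fp <- file.path(dir, "allele_freqs.tsv")
  if (file.exists(fp)) freqs <- read_freq_table(fp)
  structure(list(counts = counts, clinical = clinical, genotypes = genotypes,
                 freqs = freqs, truth = NULL, config = NULL),
            class = "disparity_dataset")
}
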
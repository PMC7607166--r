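#' Fit a single SNP-gene eQTL association
#'
#' Ordinary least squares of normalized expression on alternate-allele dosage
#' (additive coding) with a two-sided t-test on the slope. Samples with
#' missing dosage are excluded pairwise. A monomorphic SNP (fewer than two
#' distinct dosage values among non-missing samples) is flagged untestable
#' and is excluded downstream.
#'
#' @param dosages Per-sample dosages in \{0, 1, 2\} (NA = missing).
#' @param expression Per-sample normalized expression values.
#' @param snp_id,gene_id Identifiers recorded on the result.
#' @param ref,alt Allele labels recorded on the result.
#' @return One-row data frame: `snp_id`, `gene_id`, `ref`, `alt`, `slope`
#'   (log2 expression change per alt-allele copy), `p`, `increasing_allele`
#'   (`alt` if slope > 0, `ref` if slope < 0, `undetermined` if 0),
#'   `untestable`.
#' @examples
#' fit_eqtl(c(0, 1, 2, 0, 1, 2), c(0, 2, 4, 0.1, 2.1, 3.9), "rs1", "g1")
#' @export
fit_eqtl <- function(dosages, expression, snp_id = "snp", gene_id = "gene",
                     ref = "A", alt = "G") {
  ok <- !is.na(dosages) & !is.na(expression)
  d <- dosages[ok]
  e <- expression[ok]
  if (!all(d %in% c(0, 1, 2))) stopf("dosages must be 0, 1 or 2")
  rec <- data.frame(snp_id = snp_id, gene_id = gene_id, ref = ref, alt = alt,
                    slope = NA_real_, p = NA_real_,
                    increasing_allele = "undetermined", untestable = TRUE,
                    stringsAsFactors = FALSE)
  if (length(unique(d)) < 2 || length(d) < 3) return(rec)
  fit <- lm(e ~ d)
  # summary.lm warns on numerically perfect fits; the slope/p are still valid
  sm <- suppressWarnings(summary(fit)$coefficients)
  if (nrow(sm) < 2 || !is.finite(sm["d", "Pr(>|t|)"])) return(rec)
  slope <- unname(sm["d", "Estimate"])
  p <- unname(sm["d", "Pr(>|t|)"])
  rec$slope <- slope
  rec$p <- max(p, .Machine$double.xmin)
  rec$increasing_allele <- if (slope > 0) "alt" else if (slope < 0) "ref"
                           else "undetermined"
  rec$untestable <- FALSE
  rec
}

#' eQTL scan over SNP-gene pairs
#'
#' Fits [fit_eqtl()] for each requested pair and BH-adjusts p-values across
#' all testable pairs.
#'
#' @param genotypes A `genotype_matrix`.
#' @param norm Normalized expression matrix (genes x samples; shared ids).
#' @param genes Genes to test (default: all rows of `norm`); every SNP is
#'   tested against every gene unless `pairs` is given.
#' @param pairs Optional data frame with `snp_id`, `gene_id` restricting the
#'   scan to specific pairs.
#' @return Data frame of eQTL records with a `padj` column (NA for
#'   untestable pairs).
#' @export
eqtl_scan <- function(genotypes, norm, genes = rownames(norm), pairs = NULL) {
  shared <- intersect(colnames(genotypes$dosage), colnames(norm))
  if (length(shared) < 3) stopf("fewer than 3 shared samples")
  if (is.null(pairs))
    pairs <- expand.grid(snp_id = rownames(genotypes$dosage), gene_id = genes,
                         stringsAsFactors = FALSE)
  recs <- lapply(seq_len(nrow(pairs)), function(i) {
    s <- pairs$snp_id[i]; g <- pairs$gene_id[i]
    fit_eqtl(genotypes$dosage[s, shared], norm[g, shared], snp_id = s,
             gene_id = g, ref = genotypes$ref[[s]], alt = genotypes$alt[[s]])
  })
  out <- do.call(rbind, recs)
  out$padj <- NA_real_
  ok <- !out$untestable
  if (any(ok)) out$padj[ok] <- bh_adjust(out$p[ok])
  out
}

#' Per-population frequency of the expression-increasing allele
#'
#' Orients the stored alternate-allele frequencies by the eQTL effect
#' direction: if the increasing allele is the alternate allele the
#' frequencies are returned unchanged, otherwise complemented (`1 - f`).
#' This makes the downstream consistency check invariant to how ref/alt were
#' labelled.
#'
#' @param record One eQTL record (row of [eqtl_scan()] output or
#'   [read_eqtl_table()]), with a determined `increasing_allele`.
#' @param freqs Allele-frequency table (`snp_id`, `population`, `alt_freq`).
#' @return Named numeric vector: increasing-allele frequency per population.
#' @examples
#' f <- data.frame(snp_id = "rs17689585", population = c("AS", "AA", "CA"),
#'                 alt_freq = c(0.0744, 0.2247, 0.5149))
#' rec <- data.frame(snp_id = "rs17689585", increasing_allele = "alt")
#' orient_effect_allele(rec, f)
#' @export
orient_effect_allele <- function(record, freqs) {
  ia <- record$increasing_allele
  if (is.na(ia) || ia == "undetermined")
    stopf("effect-allele orientation undetermined for %s", record$snp_id)
  rows <- freqs[freqs$snp_id == record$snp_id, ]
  if (!nrow(rows)) stopf("SNP %s missing from frequency table", record$snp_id)
  f <- setNames(rows$alt_freq, rows$population)
  if (ia == "alt") f else 1 - f
}
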
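#' Library-size normalization to log2 scale
#'
#' Rescales every sample to a common target library, then log-transforms with
#' a pseudocount of one: `log2(count * target_library / column_sum + 1)`. The
#' pseudocount keeps zero counts at exactly zero, and samples with
#' proportional counts map to identical normalized columns.
#'
#' @param counts Integer gene x sample count matrix.
#' @param target_library Target library size (default 40 million reads).
#' @return Real-valued matrix of the same shape (attributes preserved).
#' @examples
#' m <- matrix(c(100L, 0L), 1, 2, dimnames = list("g1", c("a", "b")))
#' m[1, 2] <- 50L
#' normalize_log2(m, target_library = 1e7)
#' @export
normalize_log2 <- function(counts, target_library = 40e6) {
  if (target_library <= 0) stopf("`target_library` must be > 0")
  libs <- colSums(counts)
  if (any(libs <= 0)) stopf("all-zero sample column(s): %s",
                            paste(colnames(counts)[libs <= 0], collapse = ", "))
  out <- log2(sweep(counts, 2, target_library / libs, `*`) + 1)
  attr(out, "populations") <- attr(counts, "populations")
  out
}

# Vectorized two-sided Welch unequal-variance t-test across matrix rows.
# Genes constant in both groups get p = 1 (no evidence, not NaN).
row_welch <- function(m, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  ma <- rowMeans(m[, idx_a, drop = FALSE])
  mb <- rowMeans(m[, idx_b, drop = FALSE])
  va <- apply(m[, idx_a, drop = FALSE], 1, var)
  vb <- apply(m[, idx_b, drop = FALSE], 1, var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[se2 == 0] <- 1
  p[p == 0] <- .Machine$double.xmin  # keep p in (0, 1]
  list(diff = ma - mb, p = p)
}

#' Pairwise differential-expression test
#'
#' For every gene, the log2 fold change is the difference of group-mean
#' normalized values (`group` minus `reference`) and the p-value comes from a
#' two-sided Welch unequal-variance t-test; adjusted p-values are
#' Benjamini-Hochberg across all genes of this comparison. Direction is
#' `up`/`down` when the gene clears both the adjusted-p and fold-change
#' cutoffs, `nde` (not differentially expressed) otherwise.
#'
#' @param norm Normalized matrix from [normalize_log2()].
#' @param samples_A,samples_B Disjoint character vectors of sample ids; A is
#'   the comparison group, B the reference.
#' @param comparison Length-2 character vector naming (group, reference);
#'   defaults to `c("A", "B")`.
#' @param lfc_threshold Absolute log2-fold-change cutoff for calling a DEG
#'   (default 0.585, i.e. a 1.5-fold change).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return A `de_result` data frame: `gene_id`, `log2fc`, `p`, `padj`,
#'   `direction`, with the comparison stored as an attribute.
#' @export
de_test <- function(norm, samples_A, samples_B, comparison = c("A", "B"),
                    lfc_threshold = 0.585, alpha = 0.05) {
  if (length(intersect(samples_A, samples_B)))
    stopf("sample groups overlap")
  if (length(samples_A) < 2 || length(samples_B) < 2)
    stopf("both groups need >= 2 samples")
  missing <- setdiff(c(samples_A, samples_B), colnames(norm))
  if (length(missing)) stopf("samples absent from matrix: %s",
                             paste(missing, collapse = ", "))
  w <- row_welch(norm, match(samples_A, colnames(norm)),
                 match(samples_B, colnames(norm)))
  padj <- bh_adjust(w$p)
  res <- data.frame(gene_id = rownames(norm), log2fc = unname(w$diff),
                    p = unname(w$p), padj = unname(padj),
                    stringsAsFactors = FALSE)
  res$direction <- deg_direction(res$log2fc, res$padj, lfc_threshold, alpha)
  attr(res, "comparison") <- comparison
  class(res) <- c("de_result", "data.frame")
  res
}

deg_direction <- function(log2fc, padj, lfc_threshold, alpha) {
  ifelse(padj <= alpha & log2fc >= lfc_threshold, "up",
         ifelse(padj <= alpha & log2fc <= -lfc_threshold, "down", "nde"))
}

#' @export
print.de_result <- function(x, ...) {
  comp <- attr(x, "comparison")
  cat(sprintf("Differential expression: %s vs %s (reference %s), %d genes\n",
              comp[1], comp[2], comp[2], nrow(x)))
  cat(sprintf("  up: %d  down: %d  nde: %d\n", sum(x$direction == "up"),
              sum(x$direction == "down"), sum(x$direction == "nde")))
  NextMethod()
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates that all p-values lie in (0, 1] and applies the step-up
#' false-discovery-rate adjustment (sorted ascending,
#' `padj_i = min_{j >= i} n p_j / j`, capped at 1, original order restored).
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) stopf("empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stopf("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Filter a DE result to the DEG set
#'
#' Retains genes with `padj <= alpha` and `|log2fc| >= lfc_threshold`; the
#' direction is the sign of the fold change.
#'
#' @param results A `de_result` data frame.
#' @param lfc_threshold Absolute log2-fold-change cutoff (> 0).
#' @param alpha Adjusted-p cutoff (> 0).
#' @return Data frame with `gene_id` and `direction` (`up`/`down`).
#' @export
filter_degs <- function(results, lfc_threshold = 0.585, alpha = 0.05) {
  if (lfc_threshold <= 0 || alpha <= 0) stopf("thresholds must be > 0")
  keep <- results$padj <= alpha & abs(results$log2fc) >= lfc_threshold
  data.frame(gene_id = results$gene_id[keep],
             direction = ifelse(results$log2fc[keep] > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Venn decomposition of three DEG sets
#'
#' @param deg_sets Named list of three character vectors of gene ids (one per
#'   pairwise comparison).
#' @return List with `regions` (named counts for all seven Venn regions,
#'   names like `"AB"` for genes in the first two sets only) and
#'   `intersection` (genes shared by all three comparisons).
#' @export
intersect_comparisons <- function(deg_sets) {
  if (length(deg_sets) != 3 || is.null(names(deg_sets)))
    stopf("`deg_sets` must be a named list of three gene-id vectors")
  sets <- lapply(deg_sets, unique)
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  member <- matrix(member, ncol = 3)
  key <- apply(member, 1, function(r) paste(c("A", "B", "C")[r], collapse = ""))
  regions <- setNames(integer(7), c("A", "B", "C", "AB", "AC", "BC", "ABC"))
  tab <- table(key)
  regions[names(tab)] <- as.integer(tab)
  list(regions = regions,
       intersection = sort(all_genes[rowSums(member) == 3]),
       set_names = names(deg_sets))
}

#' Run the three pairwise race comparisons
#'
#' Convenience wrapper computing the comparison set the disparity analysis
#' uses: AS vs CA and AA vs CA with CA as reference, and AS vs AA with AA as
#' reference (labels taken from `comparisons`).
#'
#' @param norm Normalized matrix with a `populations` attribute, or pass
#'   `populations` explicitly.
#' @param comparisons List of length-2 character vectors `(group, reference)`.
#' @param populations Named vector mapping sample id to population.
#' @param lfc_threshold,alpha DEG thresholds forwarded to [de_test()].
#' @return Named list of `de_result` objects, names like `"AS_vs_CA"`.
#' @export
de_all_comparisons <- function(norm,
                               comparisons = list(c("AS", "CA"), c("AS", "AA"),
                                                  c("AA", "CA")),
                               populations = attr(norm, "populations"),
                               lfc_threshold = 0.585, alpha = 0.05) {
  if (is.null(populations)) stopf("`populations` required")
  out <- lapply(comparisons, function(cmp) {
    a <- names(populations)[populations == cmp[1]]
    b <- names(populations)[populations == cmp[2]]
    de_test(norm, a, b, comparison = cmp, lfc_threshold = lfc_threshold,
            alpha = alpha)
  })
  names(out) <- vapply(comparisons, function(cmp)
    paste0(cmp[1], "_vs_", cmp[2]), character(1))
  out
}
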
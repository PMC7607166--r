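# Three-source directional-consistency integration: the pipeline's core.
# A SNP-gene pair is nominated when, for every pairwise race comparison in
# which the gene is differentially expressed, the population ordering of the
# expression-increasing allele's frequency agrees with the expression
# ordering: the group with more copies of the increasing allele must be the
# group with higher expression.

#' Per-gene direction vector across the three race comparisons
#'
#' Maps each comparison's DEG call to a sign: up = +1, down = -1, NDE = 0.
#'
#' @param de_results Named list of `de_result` data frames, one per pairwise
#'   comparison (as from [de_all_comparisons()]).
#' @param gene Gene id.
#' @return Named integer vector (one element per comparison) with a
#'   `comparisons` attribute holding the (group, reference) pairs.
#' @export
build_direction_vector <- function(de_results, gene) {
  dirs <- vapply(de_results, function(res) {
    row <- res[res$gene_id == gene, , drop = FALSE]
    if (!nrow(row)) return(0L)
    switch(row$direction, up = 1L, down = -1L, 0L)
  }, integer(1))
  attr(dirs, "comparisons") <- lapply(de_results, attr, "comparison")
  dirs
}

#' Directional-consistency call for one SNP-gene pair
#'
#' For each pairwise comparison (group A vs reference B) in which the gene is
#' differentially expressed (direction d != 0), the comparison is
#' `consistent` when `sign(f_A - f_B) == d` — the group with the higher
#' frequency of the expression-increasing allele is the group with higher
#' expression — and `inconsistent` when the signs disagree. Comparisons with
#' d == 0 are `skipped_nde`; frequency gaps below `min_gap` are
#' `skipped_small_gap` (too small to trust the ordering). The verdict is
#' `consistent` only when at least one comparison was evaluated and all
#' evaluated comparisons agree; `unevaluable` when none could be evaluated.
#'
#' @param dv Direction vector from [build_direction_vector()] (its
#'   `comparisons` attribute supplies the population pairs), or a plain named
#'   integer vector accompanied by `comparisons`.
#' @param increasing_allele_freqs Named per-population frequencies of the
#'   expression-increasing allele, as from [orient_effect_allele()].
#' @param min_gap Minimum absolute frequency difference for a comparison to
#'   be evaluated (default 0.02, a guard against sampling noise in frequency
#'   tables).
#' @param comparisons Optional list of (group, reference) pairs overriding
#'   the attribute on `dv`.
#' @return An object of class `consistency_call`: per-comparison `status`,
#'   `n_evaluated`, `n_consistent`, `verdict`.
#' @examples
#' dv <- structure(c(-1L, -1L, -1L),
#'                 comparisons = list(c("AS", "CA"), c("AS", "AA"),
#'                                    c("AA", "CA")))
#' check_consistency(dv, c(AS = 0.0744, AA = 0.2247, CA = 0.5149))
#' @export
check_consistency <- function(dv, increasing_allele_freqs, min_gap = 0.02,
                              comparisons = attr(dv, "comparisons")) {
  if (min_gap < 0) stopf("`min_gap` must be >= 0")
  assert_prob(increasing_allele_freqs, "increasing-allele frequencies")
  if (is.null(comparisons)) stopf("comparison (group, reference) pairs required")
  status <- character(length(comparisons))
  names(status) <- vapply(comparisons, function(cmp)
    paste0(cmp[1], "_vs_", cmp[2]), character(1))
  for (i in seq_along(comparisons)) {
    cmp <- comparisons[[i]]
    missing_pop <- setdiff(cmp, names(increasing_allele_freqs))
    if (length(missing_pop))
      stopf("population(s) missing from frequencies: %s",
            paste(missing_pop, collapse = ", "))
    d <- dv[[i]]
    if (d == 0) {
      status[i] <- "skipped_nde"
      next
    }
    gap <- increasing_allele_freqs[[cmp[1]]] - increasing_allele_freqs[[cmp[2]]]
    if (abs(gap) < min_gap) {
      status[i] <- "skipped_small_gap"
    } else {
      status[i] <- if (sign(gap) == d) "consistent" else "inconsistent"
    }
  }
  n_eval <- sum(status %in% c("consistent", "inconsistent"))
  n_cons <- sum(status == "consistent")
  verdict <- if (n_eval == 0) "unevaluable"
             else if (n_cons == n_eval) "consistent"
             else "inconsistent"
  structure(list(status = status, n_evaluated = n_eval,
                 n_consistent = n_cons, verdict = verdict),
            class = "consistency_call")
}

#' @export
print.consistency_call <- function(x, ...) {
  cat(sprintf("Consistency call: %s (%d/%d comparisons consistent)\n",
              x$verdict, x$n_consistent, x$n_evaluated))
  for (i in seq_along(x$status))
    cat(sprintf("  %s: %s\n", names(x$status)[i], x$status[i]))
  invisible(x)
}

#' Consistency calls for a table of significant eQTL records
#'
#' Applies the eQTL significance gate (`padj <= alpha_eqtl`), orients the
#' effect allele, and runs [check_consistency()] for every surviving SNP-gene
#' pair.
#'
#' @param eqtls eQTL records with `padj` and `increasing_allele`.
#' @param de_results Named list of `de_result` objects.
#' @param freqs Allele-frequency table.
#' @param min_gap Forwarded to [check_consistency()].
#' @param alpha_eqtl eQTL significance gate (default 0.05).
#' @return Data frame: `snp_id`, `gene_id`, one status column per
#'   comparison, `n_evaluated`, `n_consistent`, `verdict`.
#' @export
consistency_scan <- function(eqtls, de_results, freqs, min_gap = 0.02,
                             alpha_eqtl = 0.05) {
  keep <- !is.na(eqtls$padj) & eqtls$padj <= alpha_eqtl &
    eqtls$increasing_allele != "undetermined"
  sig <- eqtls[keep, , drop = FALSE]
  comp_names <- vapply(de_results, function(res)
    paste0(attr(res, "comparison")[1], "_vs_", attr(res, "comparison")[2]),
    character(1))
  rows <- lapply(seq_len(nrow(sig)), function(i) {
    rec <- sig[i, ]
    dv <- build_direction_vector(de_results, rec$gene_id)
    call <- check_consistency(dv, orient_effect_allele(rec, freqs),
                              min_gap = min_gap)
    out <- data.frame(snp_id = rec$snp_id, gene_id = rec$gene_id,
                      stringsAsFactors = FALSE)
    for (j in seq_along(comp_names)) out[[comp_names[j]]] <- call$status[[j]]
    out$n_evaluated <- call$n_evaluated
    out$n_consistent <- call$n_consistent
    out$verdict <- call$verdict
    out
  })
  if (!length(rows)) {
    out <- data.frame(snp_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
    for (nm in comp_names) out[[nm]] <- character()
    out$n_evaluated <- integer(); out$n_consistent <- integer()
    out$verdict <- character()
    return(out)
  }
  do.call(rbind, rows)
}

#' Rank candidate driver SNP-gene pairs
#'
#' Candidates are genes carrying at least one verdict-consistent SNP whose
#' median-split survival test is significant (`padj <= alpha`). They are
#' ordered by number of consistent comparisons (descending), survival p-value
#' (ascending), largest absolute log2 fold change across comparisons
#' (descending), with `gene_id` then `snp_id` as final tiebreaks, giving a
#' deterministic total order. Consistent pairs without survival support are
#' kept in a secondary listing.
#'
#' @param calls Output of [consistency_scan()].
#' @param survival_results Output of [survival_scan()].
#' @param de_results Named list of `de_result` objects.
#' @param alpha Survival significance cutoff on BH-adjusted p (default 0.05).
#' @return List of class `candidate_table`: `candidates` (ranked data frame)
#'   and `consistent_only` (consistent pairs lacking survival support).
#' @export
rank_candidates <- function(calls, survival_results, de_results,
                            alpha = 0.05) {
  cons <- calls[calls$verdict == "consistent", , drop = FALSE]
  if (nrow(cons)) {
    surv <- survival_results[match(cons$gene_id, survival_results$gene_id), ]
    cons$survival_p <- surv$p
    cons$survival_padj <- surv$padj
    cons$max_abs_log2fc <- vapply(cons$gene_id, function(g)
      max(abs(vapply(de_results, function(res) {
        row <- res[res$gene_id == g, , drop = FALSE]
        if (nrow(row)) row$log2fc else 0
      }, numeric(1)))), numeric(1))
    sel <- !is.na(cons$survival_padj) & cons$survival_padj <= alpha
    ord <- function(df) df[order(-df$n_consistent, df$survival_p,
                                 -df$max_abs_log2fc, df$gene_id, df$snp_id), ]
    candidates <- ord(cons[sel, , drop = FALSE])
    if (nrow(candidates)) candidates$rank <- seq_len(nrow(candidates))
    consistent_only <- ord(cons[!sel, , drop = FALSE])
  } else {
    cons$survival_p <- numeric(0)
    cons$survival_padj <- numeric(0)
    cons$max_abs_log2fc <- numeric(0)
    candidates <- cbind(cons, rank = integer(0))
    consistent_only <- cons
  }
  structure(list(candidates = candidates, consistent_only = consistent_only),
            class = "candidate_table")
}

#' @export
print.candidate_table <- function(x, ...) {
  cat(sprintf("Candidate driver SNP-gene pairs: %d (plus %d consistent without survival support)\n",
              nrow(x$candidates), nrow(x$consistent_only)))
  if (nrow(x$candidates))
    print.data.frame(x$candidates[c("rank", "snp_id", "gene_id",
                                    "n_consistent", "survival_p")],
                     row.names = FALSE)
  invisible(x)
}

#' Select recurrently dysregulated gene families
#'
#' A family is flagged when (1) in at least one (cancer type, comparison)
#' cell two or more of its members are differentially expressed in the same
#' direction, and (2) members show that same-direction differential
#' expression in at least two distinct cancer types.
#'
#' @param deg_tables Data frame with columns `cancer_type`, `comparison`,
#'   `gene_id`, `direction` (`up`/`down`) pooling the per-cancer DEG calls.
#' @param family_map Named character vector mapping gene id to family name.
#' @return Data frame per family: `family`, `n_members_deg`,
#'   `condition1` (co-dysregulation within a cell), `condition2` (recurrence
#'   across cancers), `selected`, `direction`.
#' @export
select_recurrent_families <- function(deg_tables, family_map) {
  need <- c("cancer_type", "comparison", "gene_id", "direction")
  if (!all(need %in% names(deg_tables)))
    stopf("`deg_tables` needs columns %s", paste(need, collapse = ", "))
  unknown <- setdiff(deg_tables$gene_id, names(family_map))
  if (length(unknown))
    stopf("gene(s) missing from family map: %s",
          paste(unique(unknown), collapse = ", "))
  df <- deg_tables
  df$family <- unname(family_map[df$gene_id])
  out <- lapply(split(df, df$family), function(fam) {
    res <- data.frame(family = fam$family[1],
                      n_members_deg = length(unique(fam$gene_id)),
                      condition1 = FALSE, condition2 = FALSE,
                      selected = FALSE, direction = NA_character_,
                      stringsAsFactors = FALSE)
    for (d in c("up", "down")) {
      sub <- fam[fam$direction == d, , drop = FALSE]
      if (!nrow(sub)) next
      cells <- split(sub$gene_id, paste(sub$cancer_type, sub$comparison))
      c1 <- any(vapply(cells, function(g) length(unique(g)) >= 2, logical(1)))
      c2 <- length(unique(sub$cancer_type)) >= 2
      if (c1 && c2) {
        res$condition1 <- TRUE
        res$condition2 <- TRUE
        res$selected <- TRUE
        res$direction <- d
        break
      }
      res$condition1 <- res$condition1 || c1
      res$condition2 <- res$condition2 || c2
    }
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$family), ]
}
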
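#' Median split of expression values
#'
#' Splits samples into low and high expression groups at the median. Values
#' equal to the median go to the low group, so "high" is strictly above the
#' median.
#'
#' @param values Named numeric vector of per-sample expression.
#' @param gene Optional gene id recorded on the result.
#' @return List with `low` and `high` character vectors of sample ids (or
#'   indices when `values` is unnamed) and `median`.
#' @export
median_split <- function(values, gene = NULL) {
  if (length(values) < 4) stopf("median split needs >= 4 samples")
  if (length(unique(values)) == 1)
    stopf("constant expression: median split undefined")
  m <- median(values)
  ids <- if (is.null(names(values))) seq_along(values) else names(values)
  list(low = ids[values <= m], high = ids[values > m], median = m, gene = gene)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the
#' distinct event times, with ties aggregated in the standard `d_i / n_i`
#' step.
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators (0 = censored).
#' @return An object of class `km_curve`: `time` (ascending distinct event
#'   times), `surv`, `n_risk`, `n_event`.
#' @examples
#' km_curve(c(1, 2, 3), c(1, 1, 1))$surv
#' @export
km_curve <- function(times, events) {
  if (any(times < 0)) stopf("negative survival time")
  if (!all(events %in% c(0, 1))) stopf("`events` must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep], surv = fit$surv[keep],
                 n_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
                 n = length(times)), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d samples, %d event times, S(last) = %.3f\n",
              x$n, length(x$time),
              if (length(x$surv)) x$surv[length(x$surv)] else 1))
  invisible(x)
}

# S(t) from a km_curve at an arbitrary time point.
km_surv_at <- function(curve, t) {
  if (!length(curve$time) || t < curve$time[1]) return(1)
  curve$surv[max(which(curve$time <= t))]
}

#' Two-group log-rank test
#'
#' Chi-square (1 df) log-rank statistic comparing the event distributions of
#' two groups over their shared risk sets. When no risk set is comparable
#' (zero variance) the test is uninformative and returns p = 1 with a
#' warning.
#'
#' @param times_a,events_a Times and 0/1 event indicators of group A.
#' @param times_b,events_b Times and 0/1 event indicators of group B.
#' @return An object of class `logrank_result`: `statistic`, `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b)) stopf("both groups must be nonempty")
  if (sum(events_a) + sum(events_b) == 0) stopf("no events in either group")
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  group <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ group),
    error = function(e) NULL)
  if (is.null(sd) || !is.finite(sd$chisq)) {
    warning("log-rank variance is zero; returning p = 1")
    stat <- 0
    p <- 1
  } else {
    stat <- unname(sd$chisq)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    if (p == 0) p <- .Machine$double.xmin
  }
  structure(list(statistic = stat, p = p), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g (1 df), p = %.4g\n",
              x$statistic, x$p))
  invisible(x)
}

#' Median-split survival scan over genes
#'
#' For each gene, splits the cohort at the median normalized expression,
#' compares the low and high groups by the log-rank test, and records the
#' direction of effect as the sign of `S_high - S_low` at the last common
#' event time (negative means high expression does worse). P-values are
#' BH-adjusted across the scanned genes.
#'
#' @param norm Normalized expression matrix (genes x samples).
#' @param clinical Clinical table with `sample_id`, `time`, `event`.
#' @param genes Genes to scan (default: all rows of `norm`).
#' @return Data frame: `gene_id`, `statistic`, `p`, `padj`,
#'   `direction_of_effect` (+1, -1, or 0; NA when the split is undefined).
#' @export
survival_scan <- function(norm, clinical, genes = rownames(norm)) {
  stopifnot(all(clinical$sample_id %in% colnames(norm)))
  rows <- lapply(genes, function(g) {
    vals <- norm[g, clinical$sample_id]
    if (length(unique(vals)) == 1)
      return(data.frame(gene_id = g, statistic = NA_real_, p = NA_real_,
                        direction_of_effect = NA_real_))
    sp <- median_split(setNames(vals, clinical$sample_id), gene = g)
    lo <- clinical[clinical$sample_id %in% sp$low, ]
    hi <- clinical[clinical$sample_id %in% sp$high, ]
    lr <- tryCatch(
      logrank_test(lo$time, lo$event, hi$time, hi$event),
      error = function(e) list(statistic = NA_real_, p = NA_real_))
    dir <- NA_real_
    if (is.finite(lr$statistic)) {
      k_lo <- km_curve(lo$time, lo$event)
      k_hi <- km_curve(hi$time, hi$event)
      t_last <- min(max(c(k_lo$time, 0)), max(c(k_hi$time, 0)))
      dir <- sign(km_surv_at(k_hi, t_last) - km_surv_at(k_lo, t_last))
    }
    data.frame(gene_id = g, statistic = lr$statistic, p = lr$p,
               direction_of_effect = dir)
  })
  out <- do.call(rbind, rows)
  out$padj <- NA_real_
  ok <- is.finite(out$p)
  if (any(ok)) out$padj[ok] <- bh_adjust(out$p[ok])
  out[c("gene_id", "statistic", "p", "padj", "direction_of_effect")]
}
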
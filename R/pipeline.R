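# End-to-end orchestration: generate or load a dataset, normalize, run the
# three pairwise comparisons, DEG filter + Venn, median-split survival on the
# DEGs, eQTL scan, directional-consistency integration and candidate ranking,
# writing every stage as TSV when an output directory is given.

#' Pipeline configuration
#'
#' Either a [sim_config()] (synthetic mode) or a directory of input files
#' (see [read_dataset()]) plus every threshold the stages use.
#'
#' @param sim A `sim_config` for synthetic mode, or `NULL`.
#' @param data_dir Directory of input files for real-data mode, or `NULL`.
#' @param comparisons List of (group, reference) pairs (defaults to the
#'   AS/AA/CA design with CA as reference for AS vs CA and AA vs CA, AA as
#'   reference for AS vs AA).
#' @param match_ratio Optional named cohort-matching ratio.
#' @param lfc_threshold,alpha DEG thresholds (defaults 0.585 and 0.05).
#' @param target_library Normalization target library (default 40 million).
#' @param min_gap Consistency frequency-gap guard (default 0.02).
#' @param alpha_eqtl eQTL significance gate (default 0.05).
#' @param alpha_survival Survival significance cutoff (default 0.05).
#' @param seed Integer seed for any stage randomness.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, data_dir = NULL,
                            comparisons = list(c("AS", "CA"), c("AS", "AA"),
                                               c("AA", "CA")),
                            match_ratio = NULL,
                            lfc_threshold = 0.585, alpha = 0.05,
                            target_library = 40e6, min_gap = 0.02,
                            alpha_eqtl = 0.05, alpha_survival = 0.05,
                            seed = 1L) {
  if (is.null(sim) == is.null(data_dir))
    stopf("exactly one of `sim` or `data_dir` must be given")
  if (!is.null(sim) && !inherits(sim, "sim_config"))
    stopf("`sim` must be a sim_config")
  structure(list(sim = sim, data_dir = data_dir, comparisons = comparisons,
                 match_ratio = match_ratio, lfc_threshold = lfc_threshold,
                 alpha = alpha, target_library = target_library,
                 min_gap = min_gap, alpha_eqtl = alpha_eqtl,
                 alpha_survival = alpha_survival, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the integrative disparity pipeline
#'
#' Executes, in order: data generation or loading, library normalization,
#' the three pairwise differential-expression comparisons, DEG filtering and
#' Venn decomposition, median-split survival on the pooled DEGs, the eQTL
#' scan of every SNP against the DEGs (skipped without genotypes), the
#' directional-consistency scan (skipped without an allele-frequency table),
#' and candidate ranking. Survival is skipped with a notice when the clinical
#' table carries no events.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage result is
#'   written as TSV together with a run manifest (config hash, seed,
#'   thresholds, package version).
#' @return An object of class `disparity_run` with elements `dataset`,
#'   `de` (list of `de_result`), `degs`, `venn`, `survival`, `eqtls`,
#'   `consistency`, `candidates`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage [%s] failed: %s", name, conditionMessage(e)))
  }
  dataset <- stage("data", {
    if (!is.null(config$sim))
      simulate_cohort(config$sim, match_ratio = config$match_ratio)
    else read_dataset(config$data_dir)
  })
  norm <- stage("normalize",
                normalize_log2(dataset$counts, config$target_library))
  de <- stage("diffexpr",
              de_all_comparisons(norm, comparisons = config$comparisons,
                                 lfc_threshold = config$lfc_threshold,
                                 alpha = config$alpha))
  degs <- stage("degs", lapply(de, filter_degs,
                               lfc_threshold = config$lfc_threshold,
                               alpha = config$alpha))
  venn <- stage("venn", {
    if (length(degs) == 3)
      intersect_comparisons(lapply(degs, `[[`, "gene_id"))
    else NULL
  })
  deg_genes <- sort(unique(unlist(lapply(degs, `[[`, "gene_id"))))
  surv <- NULL
  if (sum(dataset$clinical$event) > 0 && length(deg_genes)) {
    surv <- stage("survival",
                  survival_scan(norm, dataset$clinical, genes = deg_genes))
  } else {
    message("survival stage skipped (no events or no DEGs)")
  }
  eqtls <- NULL
  if (!is.null(dataset$genotypes) && length(deg_genes)) {
    eqtls <- stage("eqtl", eqtl_scan(dataset$genotypes, norm,
                                     genes = deg_genes))
  } else {
    message("eQTL stage skipped (no genotypes or no DEGs)")
  }
  consistency <- NULL
  if (!is.null(eqtls) && !is.null(dataset$freqs)) {
    consistency <- stage("consistency",
                         consistency_scan(eqtls, de, dataset$freqs,
                                          min_gap = config$min_gap,
                                          alpha_eqtl = config$alpha_eqtl))
  }
  candidates <- NULL
  if (!is.null(consistency) && !is.null(surv)) {
    candidates <- stage("ranking",
                        rank_candidates(consistency, surv, de,
                                        alpha = config$alpha_survival))
  }
  run <- structure(list(dataset = dataset, de = de, degs = degs, venn = venn,
                        survival = surv, eqtls = eqtls,
                        consistency = consistency, candidates = candidates,
                        config = config),
                   class = "disparity_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (nm in names(run$de)) {
    res <- run$de[[nm]]
    df <- as.data.frame(res)
    for (col in c("log2fc", "p", "padj")) df[[col]] <- fmt_num(df[[col]])
    write_tsv(df, file.path(out_dir, paste0("de_", nm, ".tsv")))
  }
  if (!is.null(run$venn)) {
    venn_df <- data.frame(region = names(run$venn$regions),
                          count = as.integer(run$venn$regions))
    write_tsv(venn_df, file.path(out_dir, "venn.tsv"))
    writeLines(run$venn$intersection,
               file.path(out_dir, "intersection_genes.txt"))
  }
  if (!is.null(run$survival)) {
    df <- run$survival
    for (col in c("statistic", "p", "padj")) df[[col]] <- fmt_num(df[[col]])
    write_tsv(df, file.path(out_dir, "survival.tsv"))
  }
  if (!is.null(run$eqtls))
    write_eqtl_table(run$eqtls, file.path(out_dir, "eqtls.tsv"))
  if (!is.null(run$consistency))
    write_tsv(run$consistency, file.path(out_dir, "consistency.tsv"))
  if (!is.null(run$candidates)) {
    write_tsv(run$candidates$candidates, file.path(out_dir, "candidates.tsv"))
    write_tsv(run$candidates$consistent_only,
              file.path(out_dir, "consistent_only.tsv"))
  }
  if (!is.null(run$eqtls) && !is.null(run$dataset$genotypes)) {
    g <- run$dataset$genotypes
    ok <- !run$eqtls$untestable
    manhattan <- data.frame(snp_id = run$eqtls$snp_id[ok],
                            chrom = unname(g$chrom[run$eqtls$snp_id[ok]]),
                            pos = unname(g$pos[run$eqtls$snp_id[ok]]),
                            p = fmt_num(run$eqtls$p[ok]))
    write_tsv(manhattan, file.path(out_dir, "manhattan.tsv"))
  }
  manifest <- c(
    sprintf("package_version\t%s",
            as.character(utils::packageVersion("raceDrivers"))),
    sprintf("config_md5\t%s", config_hash(run$config)),
    sprintf("seed\t%d", run$config$seed),
    sprintf("lfc_threshold\t%g", run$config$lfc_threshold),
    sprintf("alpha\t%g", run$config$alpha),
    sprintf("target_library\t%g", run$config$target_library),
    sprintf("min_gap\t%g", run$config$min_gap),
    sprintf("alpha_eqtl\t%g", run$config$alpha_eqtl),
    sprintf("alpha_survival\t%g", run$config$alpha_survival))
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}

#' @export
print.disparity_run <- function(x, ...) {
  cat("Integrative disparity pipeline run\n")
  for (nm in names(x$de)) {
    res <- x$de[[nm]]
    cat(sprintf("  %s: %d DEGs (%d up, %d down)\n", nm,
                sum(res$direction != "nde"), sum(res$direction == "up"),
                sum(res$direction == "down")))
  }
  if (!is.null(x$venn))
    cat(sprintf("  DEGs in all three comparisons: %d\n",
                length(x$venn$intersection)))
  if (!is.null(x$consistency))
    cat(sprintf("  consistent SNP-gene pairs: %d of %d significant eQTL pairs\n",
                sum(x$consistency$verdict == "consistent"),
                nrow(x$consistency)))
  if (!is.null(x$candidates))
    cat(sprintf("  ranked candidates: %d\n", nrow(x$candidates$candidates)))
  invisible(x)
}

#' @export
summary.disparity_run <- function(object, ...) {
  print(object)
  if (!is.null(object$candidates) && nrow(object$candidates$candidates)) {
    cat("Top candidates:\n")
    print.data.frame(utils::head(
      object$candidates$candidates[c("rank", "snp_id", "gene_id",
                                     "n_consistent", "survival_p")], 5),
      row.names = FALSE)
  }
  invisible(object)
}

#' Ward-linkage leaf orders for heatmap export
#'
#' Agglomerative hierarchical clustering (Ward.D2 on Euclidean distance) of
#' the rows and columns of a matrix, returning the dendrogram leaf orders.
#'
#' @param m Numeric matrix with at least 2 rows.
#' @return List with `rows` and `cols` (integer leaf orders).
#' @export
ward_order <- function(m) {
  if (nrow(m) < 2) stopf("need at least 2 rows")
  rows <- stats::hclust(stats::dist(m), method = "ward.D2")$order
  cols <- if (ncol(m) >= 2)
    stats::hclust(stats::dist(t(m)), method = "ward.D2")$order
  else seq_len(ncol(m))
  list(rows = rows, cols = cols)
}
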
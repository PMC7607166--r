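# Shared fixtures and independent oracles, all built in code.

# Brute-force Benjamini-Hochberg step-up: sort ascending, take the running
# minimum of n * p_j / j from the largest rank down, cap at 1, restore order.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  running <- Inf
  for (j in n:1) {
    running <- min(running, n * ps[j] / j)
    adj[j] <- min(running, 1)
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Hand product-limit estimator over distinct event times.
km_brute <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_i <- sum(times >= ts[i])
    d_i <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# Small three-race config with one planted driver, used across modules.
toy_driver_config <- function(seed = 1, beta = 1.0,
                              freqs = c(AS = 0.1, AA = 0.4, CA = 0.7)) {
  sim_config(
    n_per_population = c(AS = 60, AA = 60, CA = 240),
    n_genes = 40, n_snps = 4,
    planted_drivers = list(list(snp_id = "rsDRV", gene_id = "DRV",
                                freqs = freqs,
                                eqtl_log2_effect_per_allele = beta)),
    survival_genes = list(list(gene_id = "DRV", log_hazard_per_sd = 0.8)),
    seed = seed)
}

# Fake de_result objects for integration tests, bypassing the test stage.
fake_de <- function(gene_ids, directions, log2fc, comparison) {
  res <- data.frame(gene_id = gene_ids, log2fc = log2fc, p = 1e-6,
                    padj = 1e-5, direction = directions,
                    stringsAsFactors = FALSE)
  attr(res, "comparison") <- comparison
  class(res) <- c("de_result", "data.frame")
  res
}

# The three-comparison design used throughout: CA reference for AS vs CA and
# AA vs CA, AA reference for AS vs AA.
race_comparisons <- list(c("AS", "CA"), c("AS", "AA"), c("AA", "CA"))

# Mean estimated log2 fold change for a gene planted at `effect` between two
# 300-sample groups of negative-binomial counts, averaged over seeds.
estimate_planted_lfc <- function(effect, grp, ref, seeds, n_per_group = 300) {
  ests <- vapply(seeds, function(s) {
    np <- setNames(c(n_per_group, n_per_group), c(grp, ref))
    cfg <- sim_config(n_per_population = np, n_genes = 200, n_snps = 1,
                      planted_de_only = list(list(
                        gene_id = "TARGET",
                        race_log2_shifts = setNames(effect, grp))),
                      nb_dispersion = 0.2, baseline_mean = 500, seed = s)
    counts <- simulate_expression(NULL, cfg, seed = s)
    norm <- normalize_log2(counts)
    pops <- attr(counts, "populations")
    de <- de_test(norm, names(pops)[pops == grp], names(pops)[pops == ref],
                  comparison = c(grp, ref))
    de$log2fc[de$gene_id == "TARGET"]
  }, numeric(1))
  mean(ests)
}
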
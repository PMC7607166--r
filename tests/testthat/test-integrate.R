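xkr9_freqs <- c(AS = 0.0744, AA = 0.2247, CA = 0.5149)

# DE results reproducing the pairwise patterns of the worked example: a gene
# down in all three comparisons and one down in two with one NDE.
worked_de <- function() {
  list(
    AS_vs_CA = fake_de(c("XKR9", "SIGLEC14"), c("down", "down"),
                       c(-1.6, -1.5), c("AS", "CA")),
    AS_vs_AA = fake_de(c("XKR9", "SIGLEC14"), c("down", "down"),
                       c(-1.1, -0.97), c("AS", "AA")),
    AA_vs_CA = fake_de(c("XKR9", "SIGLEC14"), c("down", "nde"),
                       c(-0.63, -0.1), c("AA", "CA")))
}

test_that("direction vectors map DEG calls to signs", {
  de <- worked_de()
  expect_equal(as.integer(build_direction_vector(de, "XKR9")),
               c(-1L, -1L, -1L))
  expect_equal(as.integer(build_direction_vector(de, "SIGLEC14")),
               c(-1L, -1L, 0L))
  expect_equal(as.integer(build_direction_vector(de, "ABSENT")),
               c(0L, 0L, 0L))
})

test_that("the worked SNP example is consistent on all three comparisons", {
  de <- worked_de()
  dv <- build_direction_vector(de, "XKR9")
  call <- check_consistency(dv, xkr9_freqs, min_gap = 0.02)
  expect_equal(unname(call$status), rep("consistent", 3))
  expect_equal(call$n_evaluated, 3L)
  expect_equal(call$verdict, "consistent")

  # flipping the effect-allele orientation flips every comparison
  flipped <- check_consistency(dv, 1 - xkr9_freqs, min_gap = 0.02)
  expect_equal(unname(flipped$status), rep("inconsistent", 3))
  expect_equal(flipped$verdict, "inconsistent")

  # NDE comparisons are skipped, the rest still evaluated
  dv2 <- build_direction_vector(de, "SIGLEC14")
  call2 <- check_consistency(dv2, xkr9_freqs, min_gap = 0.02)
  expect_equal(call2$n_evaluated, 2L)
  expect_equal(unname(call2$status[3]), "skipped_nde")
  expect_equal(call2$verdict, "consistent")

  # all NDE: unevaluable
  dv3 <- build_direction_vector(de, "ABSENT")
  expect_equal(check_consistency(dv3, xkr9_freqs)$verdict, "unevaluable")
})

test_that("growing min_gap only removes evaluated comparisons", {
  set.seed(18)
  for (i in 1:30) {
    dv <- structure(sample(c(-1L, 0L, 1L), 3, replace = TRUE),
                    comparisons = race_comparisons)
    f <- setNames(runif(3), c("AS", "AA", "CA"))
    gaps <- sort(c(0, abs(c(f["AS"] - f["CA"], f["AS"] - f["AA"],
                            f["AA"] - f["CA"])), 1))
    calls <- lapply(gaps + 1e-9, function(g) check_consistency(dv, f, g))
    n_eval <- vapply(calls, `[[`, integer(1), "n_evaluated")
    expect_true(all(diff(n_eval) <= 0))
    # a comparison never moves from inconsistent to consistent
    for (j in seq_along(calls)[-1]) {
      was_incons <- calls[[j - 1]]$status == "inconsistent"
      expect_false(any(calls[[j]]$status[was_incons] == "consistent"))
    }
  }
})

test_that("consistency verdicts survive ref/alt relabelling end-to-end", {
  ds <- simulate_cohort(toy_driver_config(seed = 19))
  norm <- normalize_log2(ds$counts)
  de <- de_all_comparisons(norm, lfc_threshold = 0.2)
  eq <- eqtl_scan(ds$genotypes, norm, genes = c("DRV", "gene0001", "gene0002"))
  calls <- consistency_scan(eq, de, ds$freqs)

  # complement stored alt frequencies and negate every slope: same verdicts
  eq2 <- eq
  eq2$slope <- -eq$slope
  eq2$increasing_allele <- c(alt = "ref", ref = "alt",
                             undetermined = "undetermined")[eq$increasing_allele]
  freqs2 <- ds$freqs
  freqs2$alt_freq <- 1 - freqs2$alt_freq
  calls2 <- consistency_scan(eq2, de, freqs2)
  expect_equal(calls$verdict, calls2$verdict)
  expect_equal(calls[names(calls) != "snp_id"], calls2[names(calls2) != "snp_id"])
})

test_that("candidate ranking gates on survival and keeps a secondary listing", {
  calls <- data.frame(snp_id = c("rs1", "rs2"), gene_id = c("g1", "g2"),
                      AS_vs_CA = "consistent", AS_vs_AA = "consistent",
                      AA_vs_CA = "consistent", n_evaluated = 3L,
                      n_consistent = 3L, verdict = "consistent",
                      stringsAsFactors = FALSE)
  surv <- data.frame(gene_id = c("g1", "g2"), statistic = c(20, 0.1),
                     p = c(1e-5, 0.8), padj = c(2e-5, 0.8),
                     direction_of_effect = c(-1, 1))
  de <- list(A = fake_de(c("g1", "g2"), c("down", "down"), c(-1, -2),
                         c("AS", "CA")))
  tab <- rank_candidates(calls, surv, de)
  expect_equal(tab$candidates$gene_id, "g1")
  expect_equal(tab$candidates$rank, 1L)
  expect_equal(tab$consistent_only$gene_id, "g2")

  # nothing consistent: both tables empty
  calls$verdict <- "inconsistent"
  tab2 <- rank_candidates(calls, surv, de)
  expect_equal(nrow(tab2$candidates), 0L)
  expect_equal(nrow(tab2$consistent_only), 0L)
})

test_that("planted drivers are called consistent and null SNPs are not", {
  hits <- 0L; nulls_ok <- 0L; n_seeds <- 6L
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(
      n_per_population = c(AS = 100, AA = 100, CA = 400),
      n_genes = 40, n_snps = 6,
      planted_drivers = list(
        list(snp_id = "rsA", gene_id = "GA",
             freqs = c(AS = 0.10, AA = 0.30, CA = 0.50),
             eqtl_log2_effect_per_allele = 0.8),
        list(snp_id = "rsB", gene_id = "GB",
             freqs = c(AS = 0.70, AA = 0.50, CA = 0.30),
             eqtl_log2_effect_per_allele = -0.9)),
      survival_genes = list(list(gene_id = "GA", log_hazard_per_sd = 0.8)),
      seed = s)
    pc <- pipeline_config(sim = cfg, lfc_threshold = 0.2, seed = s)
    run <- run_pipeline(pc)
    cons <- run$consistency
    key <- paste(cons$snp_id, cons$gene_id)
    planted <- c("rsA GA", "rsB GB")
    hits <- hits + sum(cons$verdict[key %in% planted] == "consistent")
    # null SNPs carry equal frequencies across populations, so they can
    # never clear the frequency-gap guard
    null_rows <- cons[!cons$snp_id %in% c("rsA", "rsB"), ]
    nulls_ok <- nulls_ok + as.integer(
      !any(null_rows$verdict == "consistent"))
  }
  expect_equal(hits, 2L * n_seeds)    # every planted pair recovered
  expect_equal(nulls_ok, n_seeds)     # no equal-frequency SNP passes
})

test_that("recurrent-family selection needs co-dysregulation and recurrence", {
  fam_map <- c(K1 = "KLK", K2 = "KLK", M1 = "MT", M2 = "MT",
               S1 = "SIG", S2 = "SIG", S3 = "SIG")
  degs <- data.frame(
    cancer_type = c("X", "X", "Y", "X", "X", "X", "Y", "Z"),
    comparison = "AS_vs_CA",
    gene_id = c("K1", "K2", "K1", "M1", "M2", "S1", "S2", "S3"),
    direction = c("down", "down", "down", "down", "down",
                  "down", "down", "down"),
    stringsAsFactors = FALSE)
  # KLK: two members down in X, recurrence in Y -> selected
  # MT: two members down in X only -> fails recurrence
  # SIG: one member per cancer -> fails co-dysregulation
  out <- select_recurrent_families(degs, fam_map)
  expect_equal(out$selected[out$family == "KLK"], TRUE)
  expect_equal(out$direction[out$family == "KLK"], "down")
  expect_equal(out$selected[out$family == "MT"], FALSE)
  expect_equal(out$selected[out$family == "SIG"], FALSE)

  # opposite directions do not count as a similar pattern
  degs2 <- degs
  degs2$direction[degs2$gene_id == "K2"] <- "up"
  out2 <- select_recurrent_families(degs2, fam_map)
  expect_equal(out2$selected[out2$family == "KLK"], FALSE)

  expect_error(select_recurrent_families(degs, fam_map[-1]), "family map")
})
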
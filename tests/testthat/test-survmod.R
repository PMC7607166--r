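test_that("median split sends ties to the low group", {
  sp <- median_split(c(a = 1, b = 2, c = 3, d = 4))
  expect_setequal(sp$low, c("a", "b"))
  expect_setequal(sp$high, c("c", "d"))

  sp2 <- median_split(c(a = 1, b = 2, c = 2, d = 3))
  expect_setequal(sp2$low, c("a", "b", "c"))
  expect_setequal(sp2$high, "d")

  # all-distinct even n splits evenly
  sp3 <- median_split(setNames(rnorm(20), paste0("s", 1:20)))
  expect_equal(length(sp3$low), 10L)
  expect_equal(length(sp3$high), 10L)

  expect_error(median_split(c(1, 1, 1, 1)), "constant")
  expect_error(median_split(c(1, 2, 3)), ">= 4")
})

test_that("Kaplan-Meier estimator matches hand product-limit computation", {
  # all censored: S identically 1
  k0 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_equal(length(k0$time), 0L)

  # three events, no censoring
  k1 <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k1$time, c(1, 2, 3))
  expect_equal(k1$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(k1$n_risk, c(3, 2, 1))

  # censoring at t=2 removes one from the t=3 risk set:
  # S(1) = 1 - 1/3 = 2/3; S(3) = 2/3 * (1 - 1/1) = 0
  k2 <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(k2$time, c(1, 3))
  expect_equal(k2$surv, c(2 / 3, 0))
  expect_equal(k2$n_risk, c(3, 1))

  # tied event times aggregate in one d_i/n_i step
  k3 <- km_curve(c(1, 1, 2), c(1, 1, 1))
  expect_equal(k3$surv, c(1 / 3, 0))

  expect_error(km_curve(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(11)
  t <- round(rexp(40), 2)
  k <- km_curve(t, rep(1, 40))
  brute <- km_brute(t, rep(1, 40))
  expect_equal(k$time, brute$time)
  expect_equal(k$surv, brute$surv)
  expect_equal(k$surv, vapply(k$time, function(x) mean(t > x), numeric(1)))
})

test_that("log-rank is zero for identical groups and symmetric under swap", {
  t <- c(1, 2, 3, 4, 5)
  e <- c(1, 0, 1, 1, 0)
  r <- logrank_test(t, e, t, e)
  expect_equal(r$statistic, 0, tolerance = 1e-10)
  expect_equal(r$p, 1)

  set.seed(12)
  ta <- rexp(20); ea <- rbinom(20, 1, 0.8)
  tb <- rexp(25, 1.8); eb <- rbinom(25, 1, 0.8)
  r1 <- logrank_test(ta, ea, tb, eb)
  r2 <- logrank_test(tb, eb, ta, ea)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p, r2$p)
  expect_error(logrank_test(numeric(0), numeric(0), tb, eb), "nonempty")
})

test_that("chi-square log-rank p agrees with a 10000-permutation null", {
  set.seed(13)
  ta <- rexp(15); ea <- rbinom(15, 1, 0.9)
  tb <- rexp(15, 2); eb <- rbinom(15, 1, 0.9)
  obs <- logrank_test(ta, ea, tb, eb)
  t_all <- c(ta, tb); e_all <- c(ea, eb)
  n_perm <- 10000
  set.seed(131)
  perm_stats <- vapply(seq_len(n_perm), function(i) {
    idx <- sample(30, 15)
    logrank_test(t_all[idx], e_all[idx], t_all[-idx], e_all[-idx])$statistic
  }, numeric(1))
  p_perm <- mean(perm_stats >= obs$statistic - 1e-12)
  expect_lt(abs(obs$p - p_perm), 0.02)
})

test_that("log-rank p is uniform under the generator's null hazard", {
  ps <- vapply(1:200, function(s) {
    cfg <- sim_config(n_per_population = c(A = 30, B = 30), n_genes = 5,
                      n_snps = 1, censor_rate = 0.2, seed = s)
    counts <- simulate_expression(NULL, cfg, seed = s)
    cl <- simulate_survival(counts, cfg, seed = s + 500)
    a <- cl[cl$race == "A", ]; b <- cl[cl$race == "B", ]
    logrank_test(a$time, a$event, b$time, b$event)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a positive hazard coefficient pushes the high-expression curve down", {
  worse <- vapply(1:20, function(s) {
    cfg <- sim_config(n_per_population = c(A = 600), n_genes = 10, n_snps = 1,
                      survival_genes = list(list(gene_id = "gene0001",
                                                 log_hazard_per_sd = 0.8)),
                      censor_rate = 0.2, seed = s)
    counts <- simulate_expression(NULL, cfg, seed = s)
    cl <- simulate_survival(counts, cfg, seed = s + 900)
    norm <- normalize_log2(counts)
    sp <- median_split(norm["gene0001", cl$sample_id])
    lo <- cl[cl$sample_id %in% sp$low, ]
    hi <- cl[cl$sample_id %in% sp$high, ]
    k_lo <- km_curve(lo$time, lo$event)
    k_hi <- km_curve(hi$time, hi$event)
    t_last <- min(max(k_lo$time), max(k_hi$time))
    raceDrivers:::km_surv_at(k_hi, t_last) <
      raceDrivers:::km_surv_at(k_lo, t_last)
  }, logical(1))
  expect_gte(mean(worse), 0.95)
})

test_that("survival scan flags the hazard-linked gene and reports direction", {
  cfg <- sim_config(n_per_population = c(A = 400), n_genes = 20, n_snps = 1,
                    survival_genes = list(list(gene_id = "gene0001",
                                               log_hazard_per_sd = 1.0)),
                    censor_rate = 0.2, seed = 21)
  counts <- simulate_expression(NULL, cfg, seed = 21)
  cl <- simulate_survival(counts, cfg, seed = 22)
  norm <- normalize_log2(counts)
  res <- survival_scan(norm, cl, genes = rownames(norm)[1:10])
  hit <- res[res$gene_id == "gene0001", ]
  expect_lt(hit$padj, 0.05)
  expect_equal(hit$direction_of_effect, -1)
})
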
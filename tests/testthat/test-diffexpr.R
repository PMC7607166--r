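test_that("normalization follows the target-library formula", {
  # 100 reads in a 10M library scaled to the 40M target: log2(401)
  m <- matrix(c(100L, 10e6L - 100L, 50L, 5e6L - 50L), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  norm <- normalize_log2(m)
  expect_equal(norm["g1", "s1"], log2(401))
  # zero counts stay exactly zero
  m2 <- matrix(c(0L, 10L, 0L, 20L), nrow = 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(normalize_log2(m2)["g1", ], c(s1 = 0, s2 = 0))
  # proportional columns normalize identically (scale invariance)
  expect_equal(norm[, "s1"], norm[, "s2"])
  # an all-zero sample is an error
  m2[, 2] <- 0L
  expect_error(normalize_log2(m2), "all-zero")
})

test_that("Welch test matches stats::t.test and handles degenerate genes", {
  set.seed(7)
  m <- matrix(rnorm(50 * 20, mean = 5), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20)))
  m["g01", ] <- 3  # constant in both groups
  a <- sprintf("s%02d", 1:10)
  b <- sprintf("s%02d", 11:20)
  res <- de_test(m, a, b)
  for (g in c("g05", "g20", "g44")) {
    tt <- t.test(m[g, a], m[g, b])
    expect_equal(res$p[res$gene_id == g], tt$p.value)
    expect_equal(res$log2fc[res$gene_id == g],
                 unname(tt$estimate[1] - tt$estimate[2]))
  }
  expect_equal(res$p[res$gene_id == "g01"], 1)
  expect_error(de_test(m, a, c(b, "s01")), "overlap")
  expect_error(de_test(m, "s01", b), ">= 2")
})

test_that("swapping group and reference negates fold changes, p unchanged", {
  set.seed(8)
  m <- matrix(rnorm(30 * 12), nrow = 30,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:12)))
  a <- sprintf("s%02d", 1:6)
  b <- sprintf("s%02d", 7:12)
  r1 <- de_test(m, a, b)
  r2 <- de_test(m, b, a)
  expect_equal(r1$log2fc, -r2$log2fc)
  expect_equal(r1$p, r2$p)
})

test_that("type-I error is controlled on null data", {
  cfg <- sim_config(n_per_population = c(A = 100, B = 100), n_genes = 2000,
                    n_snps = 1, seed = 17)
  counts <- simulate_expression(NULL, cfg, seed = 17)
  norm <- normalize_log2(counts)
  pops <- attr(counts, "populations")
  res <- de_test(norm, names(pops)[pops == "A"], names(pops)[pops == "B"])
  frac <- mean(res$p < 0.05)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(frac - 0.05), 4 * se)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    p <- pmax(p, 1e-12)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p))
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    # monotone: adjustment preserves p-value order
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.1, 1.1)), "\\(0, 1\\]")
  expect_error(bh_adjust(numeric(0)), "empty")
})

test_that("DEG filter applies both thresholds with sign-based direction", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(-0.60, -0.58, -2, 0.7),
                    p = 0.001, padj = c(0.01, 0.01, 0.06, 0.01),
                    stringsAsFactors = FALSE)
  out <- filter_degs(res, lfc_threshold = 0.585, alpha = 0.05)
  expect_equal(out$gene_id, c("a", "d"))
  expect_equal(out$direction, c("down", "up"))
  expect_error(filter_degs(res, lfc_threshold = 0), "> 0")
})

test_that("Venn decomposition agrees with brute-force membership", {
  v <- intersect_comparisons(list(x = c("X", "C"), y = c("X", "C"),
                                  z = c("X", "C")))
  expect_equal(unname(v$regions["ABC"]), 2L)
  expect_equal(v$intersection, c("C", "X"))

  v2 <- intersect_comparisons(list(x = "a", y = "b", z = "c"))
  expect_equal(length(v2$intersection), 0L)
  expect_equal(unname(v2$regions[c("A", "B", "C")]), c(1L, 1L, 1L))

  set.seed(10)
  genes <- sprintf("g%03d", 1:60)
  sets <- lapply(1:3, function(i) sample(genes, sample(10:40, 1)))
  names(sets) <- c("p", "q", "r")
  v3 <- intersect_comparisons(sets)
  # oracle: enumerate membership over all genes
  inter <- sort(Reduce(intersect, sets))
  expect_equal(v3$intersection, inter)
  counts <- integer(7)
  names(counts) <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  for (g in genes) {
    key <- paste(c("A", "B", "C")[c(g %in% sets$p, g %in% sets$q,
                                    g %in% sets$r)], collapse = "")
    if (nzchar(key)) counts[key] <- counts[key] + 1L
  }
  expect_equal(v3$regions, counts)
  expect_equal(sum(v3$regions), length(unique(unlist(sets))))
})

test_that("planted race shifts are recovered with small bias", {
  ests <- vapply(1:10, function(s) {
    cfg <- sim_config(n_per_population = c(A = 300, B = 300), n_genes = 100,
                      n_snps = 1,
                      planted_de_only = list(list(
                        gene_id = "TGT", race_log2_shifts = c(A = -0.8))),
                      seed = s)
    counts <- simulate_expression(NULL, cfg, seed = s)
    norm <- normalize_log2(counts)
    pops <- attr(counts, "populations")
    res <- de_test(norm, names(pops)[pops == "A"], names(pops)[pops == "B"])
    res$log2fc[res$gene_id == "TGT"]
  }, numeric(1))
  expect_lt(abs(mean(ests) - (-0.8)), 0.05)
})
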
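#' Simulation configuration for a race-structured cohort
#'
#' Bundles and validates every parameter of the synthetic-cohort generator.
#' The defaults reproduce the study design the pipeline assumes: three racial
#' groups (Asian American, African American, Caucasian American) matched
#' 1:1:4, negative-binomial RNA-seq counts with a shared dispersion, additive
#' cis-eQTL effects of planted driver SNPs, race-specific expression shifts
#' without genotype mediation, and exponential survival with a log-linear
#' hazard in standardized expression.
#'
#' @param n_per_population Named integer vector of cohort sizes; names are the
#'   population labels (default `c(AS = 289, AA = 289, CA = 1156)`, the 1:1:4
#'   matched design).
#' @param n_genes Number of genes in the count matrix (planted genes included).
#' @param n_snps Number of SNPs in the genotype panel (planted SNPs included).
#' @param planted_drivers List of driver SNP-gene pairs, each a list with
#'   `snp_id`, `gene_id`, `freqs` (named per-population alternate-allele
#'   frequencies) and `eqtl_log2_effect_per_allele` (log2 expression change per
#'   alternate-allele copy).
#' @param planted_de_only List of genes differentially expressed between races
#'   without genotype mediation, each a list with `gene_id` and
#'   `race_log2_shifts` (named per-population log2 shifts; unnamed populations
#'   shift 0).
#' @param survival_genes List of genes tied to survival, each a list with
#'   `gene_id` and `log_hazard_per_sd` (log hazard ratio per standard
#'   deviation of log2 expression).
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); must be positive.
#' @param baseline_mean Baseline expected count for an unshifted gene.
#' @param library_size_sd Standard deviation (log scale) of the lognormal
#'   per-sample library-size factor.
#' @param baseline_hazard Baseline exponential hazard rate (events per time
#'   unit); must be positive.
#' @param censor_rate Fraction of samples independently censored, in [0, 1].
#' @param cancer_types Character vector of cancer-type labels assigned to
#'   samples in rotation.
#' @param seed Integer seed; fully determines all generator output.
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_per_population = c(AS = 50, AA = 50, CA = 200),
#'                   n_genes = 100, n_snps = 5)
#' cfg
#' @export
sim_config <- function(n_per_population = c(AS = 289, AA = 289, CA = 1156),
                       n_genes = 500,
                       n_snps = 20,
                       planted_drivers = list(),
                       planted_de_only = list(),
                       survival_genes = list(),
                       nb_dispersion = 0.2,
                       baseline_mean = 500,
                       library_size_sd = 0.3,
                       baseline_hazard = 0.1,
                       censor_rate = 0.3,
                       cancer_types = "PANCAN",
                       seed = 1L) {
  if (is.null(names(n_per_population)) || any(names(n_per_population) == ""))
    stopf("`n_per_population` must be a named vector of population sizes")
  if (any(n_per_population < 1))
    stopf("all population sizes must be >= 1")
  if (nb_dispersion <= 0) stopf("`nb_dispersion` must be > 0")
  if (baseline_mean <= 0) stopf("`baseline_mean` must be > 0")
  if (baseline_hazard <= 0) stopf("`baseline_hazard` must be > 0")
  assert_prob(censor_rate, "`censor_rate`")
  pops <- names(n_per_population)
  for (d in planted_drivers) {
    stopifnot(is.list(d), !is.null(d$snp_id), !is.null(d$gene_id),
              !is.null(d$freqs), !is.null(d$eqtl_log2_effect_per_allele))
    if (!all(pops %in% names(d$freqs)))
      stopf("driver %s: `freqs` must name every population", d$snp_id)
    assert_prob(unlist(d$freqs), sprintf("driver %s frequencies", d$snp_id))
  }
  for (g in planted_de_only)
    stopifnot(is.list(g), !is.null(g$gene_id), !is.null(g$race_log2_shifts))
  for (g in survival_genes)
    stopifnot(is.list(g), !is.null(g$gene_id), !is.null(g$log_hazard_per_sd))
  ids <- c(vapply(planted_drivers, `[[`, "", "gene_id"),
           vapply(planted_de_only, `[[`, "", "gene_id"))
  if (anyDuplicated(ids))
    stopf("planted gene ids must be distinct")
  snp_ids <- vapply(planted_drivers, `[[`, "", "snp_id")
  if (anyDuplicated(snp_ids)) stopf("planted SNP ids must be distinct")
  if (length(ids) > n_genes) stopf("more planted genes than `n_genes`")
  if (length(snp_ids) > n_snps) stopf("more planted SNPs than `n_snps`")
  structure(list(
    n_per_population = n_per_population,
    populations = pops,
    n_genes = as.integer(n_genes),
    n_snps = as.integer(n_snps),
    planted_drivers = planted_drivers,
    planted_de_only = planted_de_only,
    survival_genes = survival_genes,
    nb_dispersion = nb_dispersion,
    baseline_mean = baseline_mean,
    library_size_sd = library_size_sd,
    baseline_hazard = baseline_hazard,
    censor_rate = censor_rate,
    cancer_types = cancer_types,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  populations: ",
      paste(sprintf("%s=%d", x$populations, x$n_per_population), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  genes: %d  SNPs: %d  NB dispersion: %g  baseline mean: %g\n",
              x$n_genes, x$n_snps, x$nb_dispersion, x$baseline_mean))
  cat(sprintf("  planted drivers: %d  DE-only genes: %d  survival genes: %d\n",
              length(x$planted_drivers), length(x$planted_de_only),
              length(x$survival_genes)))
  cat(sprintf("  censor rate: %g  seed: %d\n", x$censor_rate, x$seed))
  invisible(x)
}

# Gene / SNP id panels: planted ids first, then numbered fillers.
sim_gene_ids <- function(config) {
  planted <- c(vapply(config$planted_drivers, `[[`, "", "gene_id"),
               vapply(config$planted_de_only, `[[`, "", "gene_id"))
  extra <- setdiff(vapply(config$survival_genes, `[[`, "", "gene_id"), planted)
  planted <- c(planted, extra)
  if (length(planted) > config$n_genes)
    stopf("more planted genes than `n_genes`")
  n_fill <- config$n_genes - length(planted)
  fill <- setdiff(sprintf("gene%04d", seq_len(config$n_genes + length(planted))),
                  planted)
  c(planted, fill[seq_len(n_fill)])
}

sim_snp_ids <- function(config) {
  planted <- vapply(config$planted_drivers, `[[`, "", "snp_id")
  n_fill <- config$n_snps - length(planted)
  c(planted, sprintf("rsS%06d", seq_len(n_fill)))
}

#' Build the population allele-frequency table for a simulation
#'
#' Planted driver SNPs use their configured per-population frequencies; every
#' other SNP receives a single frequency drawn uniformly on [0.05, 0.95] and
#' shared by all populations, so non-driver SNPs carry no frequency signal.
#'
#' @param config A [sim_config()] object.
#' @return Data frame with columns `snp_id`, `population`, `alt_freq`
#'   (one row per SNP x population).
#' @export
sim_freq_table <- function(config) {
  snps <- sim_snp_ids(config)
  pops <- config$populations
  driver_ids <- vapply(config$planted_drivers, `[[`, "", "snp_id")
  base <- with_seed(derive_seed(config$seed, 11L),
                    runif(length(snps), 0.05, 0.95))
  freq <- matrix(rep(base, each = length(pops)), nrow = length(pops),
                 dimnames = list(pops, snps))
  for (d in config$planted_drivers)
    freq[pops, d$snp_id] <- unlist(d$freqs)[pops]
  data.frame(
    snp_id = rep(snps, each = length(pops)),
    population = rep(pops, times = length(snps)),
    alt_freq = as.vector(freq),
    stringsAsFactors = FALSE
  )
}

validate_freq_table <- function(freqs) {
  need <- c("snp_id", "population", "alt_freq")
  if (!is.data.frame(freqs) || !all(need %in% names(freqs)))
    stopf("allele-frequency table needs columns %s", paste(need, collapse = ", "))
  assert_prob(freqs$alt_freq, "`alt_freq`")
  if (anyDuplicated(freqs[c("snp_id", "population")]))
    stopf("allele-frequency table has duplicate (snp, population) rows")
  tab <- table(freqs$snp_id)
  if (length(unique(tab)) > 1)
    stopf("every SNP must be present for all populations")
  invisible(freqs)
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Draws, for every sample of every population, an alternate-allele dosage
#' `Binomial(2, f)` at that population's alternate-allele frequency, i.e.
#' independent biallelic SNPs at Hardy-Weinberg equilibrium with no linkage
#' disequilibrium.
#'
#' @param freqs Allele-frequency table (`snp_id`, `population`, `alt_freq`).
#' @param n_per_population Named vector of sample counts per population; every
#'   name must appear in `freqs$population`.
#' @param seed Integer seed.
#' @return An object of class `genotype_matrix`: list with `dosage`
#'   (SNP x sample integer matrix in \{0, 1, 2\}), `ref`/`alt` allele labels,
#'   `chrom`, `pos` (1-based), and `populations` (named vector mapping sample
#'   id to population).
#' @examples
#' f <- data.frame(snp_id = "rs1", population = c("AS", "CA"),
#'                 alt_freq = c(0.1, 0.5))
#' g <- simulate_genotypes(f, c(AS = 4, CA = 4), seed = 1)
#' g$dosage
#' @export
simulate_genotypes <- function(freqs, n_per_population, seed) {
  validate_freq_table(freqs)
  if (is.null(names(n_per_population)))
    stopf("`n_per_population` must be named")
  if (any(n_per_population < 1)) stopf("population sizes must be >= 1")
  pops <- names(n_per_population)
  missing_pop <- setdiff(pops, unique(freqs$population))
  if (length(missing_pop))
    stopf("population(s) absent from frequency table: %s",
          paste(missing_pop, collapse = ", "))
  snps <- unique(freqs$snp_id)
  fmat <- matrix(NA_real_, nrow = length(snps), ncol = length(pops),
                 dimnames = list(snps, pops))
  fmat[cbind(match(freqs$snp_id, snps), match(freqs$population, pops))] <-
    freqs$alt_freq
  sample_pop <- rep(pops, times = n_per_population)
  sample_ids <- unlist(lapply(pops, function(p)
    sprintf("%s_%04d", p, seq_len(n_per_population[[p]]))), use.names = FALSE)
  dosage <- with_seed(seed, {
    vapply(seq_along(sample_pop), function(i)
      rbinom(length(snps), 2L, fmat[, sample_pop[i]]),
      integer(length(snps)))
  })
  dosage <- matrix(as.integer(dosage), nrow = length(snps),
                   dimnames = list(snps, sample_ids))
  bases <- c("A", "C", "G", "T")
  ref <- bases[(seq_along(snps) - 1L) %% 4L + 1L]
  alt <- bases[seq_along(snps) %% 4L + 1L]
  structure(list(
    dosage = dosage,
    ref = setNames(ref, snps),
    alt = setNames(alt, snps),
    chrom = setNames(rep("1", length(snps)), snps),
    pos = setNames(seq_along(snps) * 1000L, snps),
    populations = setNames(sample_pop, sample_ids)
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d SNPs x %d samples (%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(sprintf("%s=%d", names(table(x$populations)),
                            as.integer(table(x$populations))), collapse = ", ")))
  invisible(x)
}

#' Simulate a negative-binomial RNA-seq count matrix
#'
#' For gene g and sample i the count is drawn from a negative binomial with
#' mean `baseline_mean * s_i * 2^(beta_g * dosage_i + shift_{g, race(i)})` and
#' dispersion `nb_dispersion`, where `s_i` is a lognormal library-size factor.
#' `beta_g` is the configured eQTL effect for planted driver genes and 0
#' otherwise; `shift` carries the planted genotype-independent race effects.
#'
#' @param genotypes A `genotype_matrix` (may be `NULL` when the configuration
#'   plants no drivers; sample structure is then taken from the configuration).
#' @param config A [sim_config()] object.
#' @param seed Integer seed.
#' @return Integer gene x sample count matrix with a `populations` attribute
#'   (named vector mapping sample id to population).
#' @export
simulate_expression <- function(genotypes, config, seed) {
  if (config$nb_dispersion <= 0) stopf("`nb_dispersion` must be > 0")
  genes <- sim_gene_ids(config)
  if (is.null(genotypes)) {
    if (length(config$planted_drivers))
      stopf("`genotypes` required when drivers are planted")
    pops <- config$populations
    sample_pop <- rep(pops, times = config$n_per_population)
    sample_ids <- unlist(lapply(pops, function(p)
      sprintf("%s_%04d", p, seq_len(config$n_per_population[[p]]))),
      use.names = FALSE)
    sample_pop <- setNames(sample_pop, sample_ids)
  } else {
    sample_pop <- genotypes$populations
    sample_ids <- names(sample_pop)
    for (d in config$planted_drivers)
      if (!d$snp_id %in% rownames(genotypes$dosage))
        stopf("planted driver SNP %s absent from genotypes", d$snp_id)
  }
  n <- length(sample_ids)
  # log2-scale offset per gene x sample
  offset <- matrix(0, nrow = length(genes), ncol = n,
                   dimnames = list(genes, sample_ids))
  for (d in config$planted_drivers)
    offset[d$gene_id, ] <- offset[d$gene_id, ] +
      d$eqtl_log2_effect_per_allele * genotypes$dosage[d$snp_id, sample_ids]
  for (g in config$planted_de_only) {
    sh <- unlist(g$race_log2_shifts)
    shifts <- ifelse(sample_pop %in% names(sh), sh[sample_pop], 0)
    offset[g$gene_id, ] <- offset[g$gene_id, ] + shifts
  }
  counts <- with_seed(seed, {
    s <- rlnorm(n, meanlog = 0, sdlog = config$library_size_sd)
    mu <- config$baseline_mean * rep(s, each = length(genes)) * 2^offset
    matrix(rnbinom(length(genes) * n, mu = mu, size = 1 / config$nb_dispersion),
           nrow = length(genes), dimnames = list(genes, sample_ids))
  })
  storage.mode(counts) <- "integer"
  attr(counts, "populations") <- sample_pop
  counts
}

#' Simulate survival outcomes linked to expression
#'
#' Survival time is exponential with rate
#' `baseline_hazard * exp(sum_g theta_g * z_g(i))` where `z_g` is the per-gene
#' standardized log2(count + 1) and `theta_g` the configured log hazard per
#' standard deviation. Each sample is independently censored with probability
#' `censor_rate`; a censored sample's time is drawn uniformly on (0, t).
#'
#' @param expr Count matrix from [simulate_expression()] (its `populations`
#'   attribute supplies the race labels).
#' @param config A [sim_config()] object.
#' @param seed Integer seed.
#' @return Clinical data frame: `sample_id`, `race`, `cancer_type`, `time`,
#'   `event`.
#' @export
simulate_survival <- function(expr, config, seed) {
  if (config$baseline_hazard <= 0) stopf("`baseline_hazard` must be > 0")
  pops <- attr(expr, "populations")
  if (is.null(pops)) stopf("`expr` lacks a `populations` attribute")
  for (g in config$survival_genes)
    if (!g$gene_id %in% rownames(expr))
      stopf("survival gene %s absent from expression matrix", g$gene_id)
  n <- ncol(expr)
  eta <- rep(0, n)
  for (g in config$survival_genes) {
    x <- log2(expr[g$gene_id, ] + 1)
    s <- sd(x)
    z <- if (s > 0) (x - mean(x)) / s else rep(0, n)
    eta <- eta + g$log_hazard_per_sd * z
  }
  with_seed(seed, {
    time <- rexp(n, rate = config$baseline_hazard * exp(eta))
    cens <- runif(n) < config$censor_rate
    time[cens] <- runif(sum(cens), 0, time[cens])
    data.frame(
      sample_id = colnames(expr),
      race = unname(pops[colnames(expr)]),
      cancer_type = rep_len(config$cancer_types, n),
      time = time,
      event = as.integer(!cens),
      stringsAsFactors = FALSE
    )
  })
}

#' Downsample a cohort to an exact population ratio
#'
#' Retains `k * ratio[p]` samples of each population `p`, with `k` the largest
#' integer the available samples allow; surplus samples are dropped by
#' seed-deterministic sampling without replacement. Row order of retained
#' samples is stable.
#'
#' @param clinical Clinical data frame with a `race` column.
#' @param ratio Named integer vector, e.g. `c(AS = 1, AA = 1, CA = 4)`.
#' @param seed Integer seed.
#' @return The downsampled clinical data frame.
#' @examples
#' cl <- data.frame(sample_id = paste0("s", 1:63),
#'                  race = rep(c("AS", "AA", "CA"), c(10, 10, 43)),
#'                  cancer_type = "PANCAN", time = 1, event = 1)
#' table(assemble_matched_cohort(cl, c(AS = 1, AA = 1, CA = 4), seed = 1)$race)
#' @export
assemble_matched_cohort <- function(clinical, ratio, seed) {
  if (is.null(names(ratio)) || any(ratio < 1))
    stopf("`ratio` must be a named vector of integers >= 1")
  counts <- table(clinical$race)
  missing_pop <- setdiff(names(ratio), names(counts))
  if (length(missing_pop))
    stopf("population(s) absent from clinical table: %s",
          paste(missing_pop, collapse = ", "))
  k <- min(floor(as.integer(counts[names(ratio)]) / as.integer(ratio)))
  if (k < 1) stopf("not enough samples to honour the ratio")
  keep <- with_seed(seed, {
    unlist(lapply(names(ratio), function(p) {
      idx <- which(clinical$race == p)
      sort(sample(idx, k * ratio[[p]]))
    }), use.names = FALSE)
  })
  clinical[sort(keep), , drop = FALSE]
}

#' Simulate a complete cohort dataset
#'
#' Runs the full generator: allele-frequency table, Hardy-Weinberg genotypes,
#' negative-binomial expression with planted drivers and race shifts,
#' expression-linked survival, and (optionally) 1:1:4-style race matching.
#' All stage seeds derive from `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @param match_ratio Optional named ratio passed to
#'   [assemble_matched_cohort()]; `NULL` keeps all samples.
#' @return An object of class `disparity_dataset`: list with `counts`,
#'   `clinical`, `genotypes`, `freqs`, and `truth` (data frame of planted
#'   driver SNP-gene pairs with their effects, for recovery scoring).
#' @examples
#' cfg <- sim_config(n_per_population = c(AS = 20, AA = 20, CA = 80),
#'                   n_genes = 50, n_snps = 4, seed = 7)
#' ds <- simulate_cohort(cfg)
#' dim(ds$counts)
#' @export
simulate_cohort <- function(config, match_ratio = NULL) {
  freqs <- sim_freq_table(config)
  genotypes <- simulate_genotypes(freqs, config$n_per_population,
                                  derive_seed(config$seed, 1L))
  counts <- simulate_expression(genotypes, config, derive_seed(config$seed, 2L))
  clinical <- simulate_survival(counts, config, derive_seed(config$seed, 3L))
  if (!is.null(match_ratio)) {
    clinical <- assemble_matched_cohort(clinical, match_ratio,
                                        derive_seed(config$seed, 4L))
    keep <- clinical$sample_id
    pops <- attr(counts, "populations")
    counts <- counts[, keep, drop = FALSE]
    attr(counts, "populations") <- pops[keep]
    genotypes$dosage <- genotypes$dosage[, keep, drop = FALSE]
    genotypes$populations <- genotypes$populations[keep]
  }
  truth <- if (length(config$planted_drivers)) {
    do.call(rbind, lapply(config$planted_drivers, function(d)
      data.frame(snp_id = d$snp_id, gene_id = d$gene_id,
                 eqtl_log2_effect_per_allele = d$eqtl_log2_effect_per_allele,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(snp_id = character(), gene_id = character(),
               eqtl_log2_effect_per_allele = numeric())
  }
  structure(list(counts = counts, clinical = clinical, genotypes = genotypes,
                 freqs = freqs, truth = truth, config = config),
            class = "disparity_dataset")
}

#' @export
print.disparity_dataset <- function(x, ...) {
  cat(sprintf("Synthetic disparity dataset: %d genes x %d samples, %d SNPs\n",
              nrow(x$counts), ncol(x$counts), nrow(x$genotypes$dosage)))
  cat("  races: ",
      paste(sprintf("%s=%d", names(table(x$clinical$race)),
                    as.integer(table(x$clinical$race))), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  planted drivers: %d\n", nrow(x$truth)))
  invisible(x)
}

#' Simulate multi-omic layers with a planted correlation structure
#'
#' Builds four continuous layers (mRNA, microRNA, DNA methylation, protein)
#' around a seed transcript using a Gaussian construction: a variable planted
#' at correlation `r` to an anchor `A` is `r * A + sqrt(1 - r^2) * noise`.
#' mRNA variables anchor on the seed transcript; variables of the other layers
#' anchor on the first planted transcript, mirroring the two-stage
#' correlation-threshold selection the feature-selection step performs.
#'
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param mrna_r,mirna_r,meth_r,protein_r Numeric vectors of target
#'   correlations, one per variable in the layer. Defaults plant 6 transcripts
#'   above 0.38, 10 microRNAs above 0.45, 10 methylation regions above 0.40
#'   and 3 proteins above 0.30, each alongside low-correlation decoys.
#' @return An object of class `omics_layers`: list with `data` (sample x
#'   variable matrix), `layer` (named vector mapping variable to layer) and
#'   `seed_gene` (the seed transcript id).
#' @export
simulate_omics_layers <- function(n_samples = 2000, seed = 1,
                                  mrna_r = c(rep(0.65, 6), rep(0.08, 14)),
                                  mirna_r = c(rep(0.70, 10), rep(0.08, 10)),
                                  meth_r = c(rep(0.65, 10), rep(0.08, 10)),
                                  protein_r = c(rep(0.55, 3), rep(0.05, 7))) {
  with_seed(seed, {
    anchor_var <- function(anchor, r)
      r * anchor + sqrt(1 - r^2) * rnorm(length(anchor))
    seed_expr <- rnorm(n_samples)
    mrna <- vapply(mrna_r, function(r) anchor_var(seed_expr, r),
                   numeric(n_samples))
    colnames(mrna) <- sprintf("mrna%02d", seq_along(mrna_r))
    t1 <- mrna[, 1]
    build <- function(rs, prefix) {
      m <- vapply(rs, function(r) anchor_var(t1, r), numeric(n_samples))
      colnames(m) <- sprintf("%s%02d", prefix, seq_along(rs))
      m
    }
    mirna <- build(mirna_r, "mir")
    meth <- build(meth_r, "meth")
    prot <- build(protein_r, "prot")
    data <- cbind(seedgene = seed_expr, mrna, mirna, meth, prot)
    rownames(data) <- sprintf("s%04d", seq_len(n_samples))
    layer <- setNames(
      c("mRNA", rep("mRNA", ncol(mrna)), rep("miRNA", ncol(mirna)),
        rep("methylation", ncol(meth)), rep("protein", ncol(prot))),
      colnames(data))
    structure(list(data = data, layer = layer, seed_gene = "seedgene"),
              class = "omics_layers")
  })
}
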
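---
title: "Nominating genetic drivers of cancer racial disparity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating genetic drivers of cancer racial disparity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raceDrivers)
```

## The problem

Tumor gene expression differs systematically between racial groups in many
cancers, but differential expression alone cannot say whether a difference is
driven by genetics. One mechanism that can: a regulatory SNP (an eQTL) whose
allele frequencies differ between populations. If allele *a* increases
expression of gene *g*, and *a* is more common in population P1 than in P2,
then *g* should be expressed more highly in P1 — and if the observed
differential expression points the other way, that SNP cannot explain it.

`raceDrivers` implements this three-source directional-consistency procedure
as a closed, testable pipeline. Because the real inputs (consortium RNA-seq,
eQTL and population-genetics resources) are access-restricted, the package
ships a synthetic-cohort generator that plants driver SNP–gene pairs with
known effects; recovering those plants is the package's acceptance surface.
All stages also accept user-supplied files in plain formats (count TSV,
clinical TSV, minimal VCF, eQTL TSV, allele-frequency TSV).

## The consistency calculus

For a SNP–gene pair, three independent observations must agree for every
pairwise race comparison (group A vs reference B) in which the gene is
differentially expressed:

1. **DE direction** `d ∈ {+1, −1}` from the race-stratified comparison;
2. **eQTL effect direction**, collapsed into the *expression-increasing
   allele* (the alt allele when the dosage slope is positive, ref when
   negative);
3. **population frequency ordering** of that increasing allele,
   `sign(f_A − f_B)`.

A comparison is *consistent* when `sign(f_A − f_B) = d`. Comparisons where
the gene is not differentially expressed are skipped (`skipped_nde`), as are
comparisons whose frequency gap is below `min_gap` (`skipped_small_gap`).
The pair's verdict is `consistent` only when at least one comparison was
evaluated and *all* evaluated comparisons agree — partial agreement is
reported with its counts but never promoted. Working in terms of the
oriented increasing allele makes every verdict invariant to how ref/alt were
labelled (complementing all stored frequencies while negating all slopes
changes nothing), which the test suite checks end-to-end; it also sidesteps
the ambiguity of which population's "major allele" one should mean.

Whether a gene NDE in one comparison should disqualify a pair was genuinely
open; we skip rather than fail such comparisons, because reported candidate
genes routinely show exactly that pattern (strong DE in two comparisons,
NDE in the third).

## Pipeline stages and their parameters

* **Normalization** — `normalize_log2()`: counts are rescaled to a common
  target library (default 40 million reads) and transformed as
  `log2(scaled + 1)`. The pseudocount keeps zeros at zero and is applied
  after scaling so proportional samples normalize identically.
* **Differential expression** — `de_test()`: per-gene Welch unequal-variance
  t-test on normalized values; `log2fc` is the difference of group means
  (group − reference), matching the thresholding semantics downstream.
  This is a deliberately self-contained, seedable stand-in for
  moderated-variance DE frameworks; it needs no dispersion estimation and
  its null behavior is verified by simulation (type-I fraction, antisymmetry
  under group swap). Zero-variance genes get p = 1, not NaN. Defaults:
  `lfc_threshold = 0.585` (a 1.5-fold change; per-cancer analyses
  conventionally use 1.0, i.e. 2-fold) and `alpha = 0.05` on
  Benjamini–Hochberg adjusted p-values, adjusted within each comparison
  separately. The reference conventions are CA for AS vs CA and AA vs CA,
  and AA for AS vs AA.
* **Survival** — `median_split()` + `km_curve()` + `logrank_test()` (backed
  by the survival package): samples split at the median expression, ties to
  the low group so "high" is strictly above the median; two-group log-rank
  with a chi-square 1-df p-value. The scan reports the sign of
  `S_high − S_low` at the last common event time as the direction of effect.
* **eQTL** — `fit_eqtl()`: OLS of expression on dosage, additive coding, no
  dominance term; monomorphic SNPs are flagged untestable. A significance
  gate (`alpha_eqtl = 0.05`, BH across tested pairs) is applied before a SNP
  enters the consistency stage — public eQTL resources are pre-thresholded,
  so the synthetic path must gate explicitly to be comparable. No cis-window
  filter is enforced because the generator assigns SNP–gene pairs
  explicitly; users with positional data can pre-filter their pair list.
* **Consistency** — `check_consistency()` / `consistency_scan()` as above.
  `min_gap` defaults to 0.02: the procedure requires a frequency *ordering*,
  and orderings inside sampling noise of a frequency table are not evidence.
* **Ranking** — `rank_candidates()`: candidates are consistent pairs whose
  gene also passes the survival gate (`alpha_survival = 0.05` on adjusted
  log-rank p); ordered by consistent-comparison count, then survival p, then
  largest |log2fc|, then ids. The ordering rule is the package's own — the
  original analysis inspected results manually — and exists to make runs
  deterministic and comparable.

## The synthetic-cohort generator

`sim_config()` fixes the study conditions; `simulate_cohort()` executes them:

* **Cohort** — default 289/289/1156 AS/AA/CA, the 1:1:4 race-matched design;
  `assemble_matched_cohort()` downsamples surplus groups (never oversamples)
  to the exact ratio with the largest feasible multiplier.
* **Genotypes** — independent biallelic SNPs at Hardy–Weinberg equilibrium:
  dosage ~ Binomial(2, f) at each population's alternate-allele frequency.
  No linkage disequilibrium and no admixture are modelled.
* **Expression** — negative-binomial counts, mean
  `baseline_mean · s_i · 2^(β·dosage + shift_race)` with a single shared
  dispersion (default 0.2) and lognormal library-size factors (σ = 0.3,
  mean-log 0): the simplest model reproducing RNA-seq overdispersion and
  library variation. Driver genes get their β from the planted eQTL effect;
  `planted_de_only` genes get race shifts without genotype mediation. This
  construction makes the consistency triad hold *mechanically* for planted
  drivers: the group with more increasing-allele copies has higher expected
  expression by construction.
* **Survival** — exponential times with rate
  `baseline_hazard · exp(Σ θ_g z_g)`, `z` the standardized log2 expression:
  a minimal proportional-hazards generator, sufficient for median-split
  log-rank testing. Censoring is independent with probability `censor_rate`
  (default 0.3), the censored time drawn uniformly below the event time.
* **Determinism** — every stochastic operation takes an explicit seed and
  restores the caller's RNG state; `simulate_cohort()` derives per-stage
  seeds from `config$seed`, so the same configuration is byte-identical
  across runs.

What the generator does **not** emulate: batch effects, gene–gene
correlation beyond genotype mediation, LD structure, admixed individuals,
per-gene dispersions, non-proportional hazards, and informative censoring.
Passing tests therefore demonstrate that the pipeline's inference machinery
is correct under its stated assumptions, not that it is robust to every
pathology of real consortium data.

## Multi-omic network module

Around a seed transcript, `select_features()` applies the two-stage
correlation screen: transcripts with |Pearson r| to the seed above the mRNA
threshold (default 0.38), then microRNA, methylation and protein variables
with |r| above their layer thresholds (0.45, 0.40, 0.30) to *any* selected
transcript. Pearson correlation is the default (the choice was open;
Spearman is exposed via `method`). Lowering any threshold never shrinks the
selected set.

`hill_climb()` learns a Bayesian network over the selected variables with a
linear-Gaussian BIC score (`bic_score()`): per node, the OLS log-likelihood
given its parents minus `(k/2)·log n`. All layers are treated as continuous
— the simplest decomposable score supporting mixed continuous multi-omic
data — with a max in-degree of 3 to bound overfitting at small n, and no
layer-direction constraints by default. The learner is a documented
stand-in: greedy add/delete/reverse moves with seeded random restarts
(default 20) and lexicographic tie-breaking, not a reimplementation of any
published structure-learning package. Its guarantees are correspondingly
modest and are what the tests assert: the output is always a DAG, the score
never decreases within a climb and never falls below the empty graph, and
on strong chain/independence simulations the *skeleton* is recovered — edge
orientations beyond Markov equivalence are deliberately never asserted.

## Numerical choices and degenerate inputs

* p-values are clamped to the smallest positive double rather than 0, so
  every p lies in (0, 1] and BH input validation is exact.
* Constant-expression genes: DE p = 1; median split refuses (undefined);
  survival scan records NA for such genes.
* Log-rank with no comparable risk sets returns p = 1 with a warning rather
  than NaN.
* Multi-allelic VCF records are rejected with a clear error — the
  consistency calculus is biallelic, and a loud failure beats silently
  splitting records. Missing genotypes (`./.`) are excluded pairwise from
  eQTL fits. VCF positions stay 1-based throughout; nothing converts to
  0-based coordinates.
* Ward clustering for heatmap export uses Ward.D2 (squared-Euclidean
  update), the common modern convention.
* `hclust`-style leaf orders, BH, log-rank and KM are delegated to base R
  and the survival package; the consistency calculus, generator, BIC scorer
  and hill climber are implemented here.

## Problem sizes used in the test suite

The suite exercises the pipeline at desk scale, chosen so each property has
clear resolution: type-I checks use 2000 null genes; fold-change recovery
uses 300 samples per group and 10 seeds (standard error of the mean
estimate ≈ 0.02 log2 units against a ±0.1 band); Hardy–Weinberg recovery
uses panels of 5000 (binomial SE ≈ 0.005); end-to-end driver recovery uses
40 genes × 600 samples over 20 seeds; network recovery uses n = 1000 with
3–5 restarts. End-to-end recovery simulations plant adjacent-population
frequency gaps of 0.2 with |β| = 0.8, giving an AS-vs-CA mediated shift of
0.64 log2 units — comfortably detectable through the BH gate at these
sample sizes, so a failure indicates a defect rather than sampling noise.
These recovery scans run at `lfc_threshold = 0.2`: genotype-mediated shifts
scale with 2β·Δf and sit well below the 1.5-fold screening cutoff, which
targets much larger race effects; the screening default remains 0.585.

## A worked synthetic example

```{r example, eval = FALSE}
cfg <- sim_config(
  n_per_population = c(AS = 100, AA = 100, CA = 400),
  n_genes = 40, n_snps = 6,
  planted_drivers = list(list(
    snp_id = "rsDRV", gene_id = "DRV",
    freqs = c(AS = 0.15, AA = 0.35, CA = 0.55),
    eqtl_log2_effect_per_allele = 0.8)),
  survival_genes = list(list(gene_id = "DRV", log_hazard_per_sd = 0.8)),
  seed = 1)
run <- run_pipeline(pipeline_config(sim = cfg, lfc_threshold = 0.2, seed = 1))
summary(run)
```

The planted pair `rsDRV`–`DRV` appears in `run$candidates$candidates` with
verdict `consistent`; SNPs with equal frequencies across populations never
clear the frequency-gap guard and end `unevaluable`.

## Known limitations

* The Welch-t DE stage has no variance moderation; at very small group
  sizes (< 10) moderated frameworks will be better calibrated.
* The consistency procedure cannot distinguish a causal regulatory SNP from
  any SNP whose frequency gradient parallels the expression gradient —
  population stratification produces directionally consistent non-causal
  pairs, exactly as it does on real data. The verdict is a screen, not a
  causal claim.
* The hill climber recovers skeletons, not orientations, and its score
  assumes linear-Gaussian local models.
* Pathway analysis, coding-consequence prediction, literature mining and
  figure rendering are out of scope; stage outputs are TSVs designed to
  feed such tools.
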
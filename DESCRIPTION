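Package: raceDrivers
Title: Integrative Nomination of Genetic Drivers of Cancer Racial Disparity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates race-structured cancer cohorts with planted
    expression-driver SNPs and runs an integrative disparity analysis:
    race-stratified pairwise differential expression on library-normalized
    RNA-seq counts, Kaplan-Meier median-split survival stratification with
    log-rank testing, per-SNP eQTL scans on genotype dosage, and a
    three-source directional-consistency procedure that nominates candidate
    driver SNP-gene pairs by requiring agreement among differential
    expression direction, eQTL effect direction, and population allele
    frequency ordering. Also provides correlation-thresholded multi-omic
    feature selection around a seed gene and BIC-scored Bayesian-network
    structure learning by greedy hill climbing, plus readers and writers for
    the simple tabular and VCF formats the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, survival, vcfR, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
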
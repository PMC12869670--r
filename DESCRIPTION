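Package: merlinmr
Title: Mendelian Randomization with Gene-Environment Interaction from
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint estimation of the average causal effect of an exposure on
    an outcome and of its modification by an environmental variable (the
    causal interaction) from four sets of genome-wide summary statistics:
    exposure GWAS, exposure gene-environment interaction study (GWIS),
    outcome GWAS and outcome GWIS. Estimation uses a Bayesian hierarchical
    model over the summary-statistics Gaussian likelihood under linkage
    disequilibrium, sampled by a blocked Gibbs sampler. Includes instrument
    selection with dual GWAS/GWIS significance thresholds and LD clumping,
    harmonization and quality-control of summary-statistics tables,
    stratified-to-GWIS transformations and inverse-variance-weighted
    meta-combination, classical IVW and MR-Egger comparators, and a
    synthetic cohort simulator with a per-SNP association engine for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
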
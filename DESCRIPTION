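Package: mrmediate
Title: Mendelian Randomisation Mediation Analysis for Summary and Individual-Level Genetic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating how much of a causal exposure effect on a
    binary disease outcome is transmitted through intermediate risk factors,
    using genetic variants as instruments. Implements two-sample Mendelian
    randomisation from GWAS summary statistics (Wald ratio, fixed-effect
    inverse-variance weighting, MR-Egger, weighted median, and regression-based
    multivariable MR), two-step MR mediation via the product of coefficients
    and the difference method, one-sample MR with weighted allele scores, and
    observational regression mediation with bootstrap uncertainty. Includes
    summary-statistic harmonisation, greedy LD clumping, per-SD rescaling, and
    a genotype-phenotype cohort simulator with closed-form ground truth for
    every mediation estimand, designed around the education to
    {body mass index, systolic blood pressure, lifetime smoking} to
    cardiovascular disease causal chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
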
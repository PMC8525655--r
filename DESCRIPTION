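Package: drarisk
Title: Doubly-Robust Additive Risk Estimation for Continuous Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a doubly-robust pipeline for estimating additive
    (risk-difference) effects of long-term continuous environmental exposures
    on annual mortality in large open cohorts. Provides generalized-propensity-score
    stabilized inverse-probability weighting for continuous exposures, weighted
    linear probability outcome models with heteroscedasticity-robust (sandwich)
    variance, split-sample estimation pooled by fixed-effects meta-analysis,
    cohort restriction rules for low-concentration analyses, covariate balance
    diagnostics based on weighted correlations, attributable-case and E-value
    effect summaries, stratified effect-measure-modification analyses, and a
    synthetic open-cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
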
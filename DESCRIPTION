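Package: fractrial
Title: Bayesian Fractional-Additivity Models for Adaptive Combination-Treatment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and simulation of three-arm response-adaptive randomized
    clinical trials of combination treatments under a Bayesian
    fractional-additivity model, in which the combination's log-odds effect is
    the better single agent's effect plus a fraction of the weaker agent's.
    Provides the effect model, a patient-level outcome simulator with
    prognostic-imbalance offsets, posterior inference for fractional,
    conventional, and full-additivity analysis models via an adaptive
    Metropolis sampler on binomial sufficient statistics, the adaptive trial
    engine (square-root probability-of-superiority allocation, arm dropping,
    early stopping at interim looks), fixed-design two-proportion sample-size
    calculations, and operating-characteristic metrics (expected proportion of
    failures, expected sample size, termination distribution, root mean
    squared error) aggregated over simulated trials.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
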
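Package: kicksyn
Title: Muscle Synergy Analysis of Cyclic Kick Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing multichannel surface electromyography (sEMG)
    recorded during cyclic lower-limb movements such as the freestyle flutter
    kick. The package covers the full workflow: Butterworth band-pass filtering
    and linear-envelope extraction, normalisation to maximum voluntary
    contraction (MVC) and to a 100-point cycle, phase-wise integrated EMG and
    root-mean-square amplitude, muscle-synergy extraction by non-negative
    matrix factorisation with variance-accounted-for model-order selection,
    K-means clustering of synergy weights with Gap-statistic cluster-count
    selection, correlation-threshold matching to reference synergies,
    activation-timing metrics, and a 2x2 mixed repeated-measures ANOVA with
    partial eta squared. A seeded synthetic-data generator emulates the
    recording structure of a two-group pre/post training study so that every
    stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
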
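Package: eegfatigue
Title: Driver-Fatigue Detection from Forehead EEG via Multi-Entropy Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting driver fatigue from
    two-channel forehead (FP1/FP2) electroencephalography. Provides
    preprocessing (notch and band-pass filtering, wavelet soft-threshold
    denoising, variance-based artifact gating, per-epoch min-max
    normalisation, 1-second epoching), nine per-epoch entropy features
    (approximate, sample, fuzzy, second-order Kolmogorov, permutation,
    spectral, symbolic transfer, wavelet log-energy and wavelet-packet
    energy entropy) plus an FFT relative-band-power baseline,
    correlation-based feature pruning, a stacking classifier combining
    logistic regression, an extreme learning machine and gradient-boosted
    trees, and leave-one-subject-out cross-validation with accuracy,
    sensitivity, specificity, F1 and ROC/AUC reporting. A synthetic
    two-state EEG cohort generator with controllable spectral, regularity
    and cross-channel coupling effects makes the whole pipeline testable
    without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
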
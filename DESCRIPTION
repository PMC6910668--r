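Package: somnoshift
Title: Sleep Scoring with Mixture Z-Scoring Under Label Shift
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Automated rodent sleep scoring from EEG/EMG recordings with a
    standardization method, mixture z-scoring, that removes affine nuisance
    variability between subjects while preserving class-balance (label-shift)
    variability. Provides multitaper spectrogram and EMG feature extraction, a
    compact convolutional sleep-stage classifier, programmatic class-balance
    rebalancing with total variation distance evaluation, bootstrap confidence
    intervals for state occupancy, and a synthetic-recording generator with
    stage-dependent spectral signatures for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    data.table
Config/testthat/edition: 3
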
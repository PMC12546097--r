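Package: flavorboost
Title: EEG-Based Prediction of Flavor Attribute Intensity with Boosted Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for decoding perceived flavor
    intensity from tasting-trial electroencephalography (EEG). Provides a
    synthetic expert tasting-panel generator (multichannel EEG epochs with
    1/f background, occipital alpha, and band-power effects coupled to latent
    attribute intensities, plus noisy 0-10 ratings); spectral and temporal
    feature extraction (Welch power spectral densities, individual alpha
    frequency, subject-specific frequency bands, normalized band powers, and
    Hjorth activity/mobility/complexity); trial-wise feature-table assembly
    with tasting-versus-rinse normalization and subject-wise standardization;
    a least-squares boosted-tree regressor with exact greedy best-first trees
    (compiled core) plus mean and lasso benchmarks; Bayesian hyperparameter
    optimization (Gaussian-process surrogate, expected improvement) under
    leave-one-subject-out cross-validation; and model comparison via Cohen's d
    with noncentral-t confidence intervals and impurity-based feature
    importance aggregated into scalp topographies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    lhs,
    pracma,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
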
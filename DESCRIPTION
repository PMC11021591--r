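Package: ictalnet
Title: Seizure Detection from Multichannel EEG with Adversarial and Mixup
    Data Augmentation
Version: 0.1.0
Authors@R:
    person("ictalnet", "developers", email = "ictalnet@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for window-based epileptic seizure detection
    from multichannel scalp EEG. Reads European Data Format (EDF) recordings
    with plain-text seizure annotations, segments them into fixed-length
    labelled windows, amplifies the training set with adversarial (fast
    gradient sign) and mixup augmentation, and classifies windows with a
    compact one-dimensional convolutional network followed by scaled
    dot-product attention over the pooled feature sequence and a gated
    recurrent unit, trained with Adam on binary cross-entropy. Includes a
    seeded synthetic EEG generator with annotated spike-wave seizure
    intervals so the whole pipeline is testable offline, plus
    confusion-matrix metrics, ROC construction, trapezoid AUC and an
    experiment runner for the augmentation-multiplier grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
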
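Package: oddballEEG
Title: Robust Auditory-Oddball ERP Features and Classification for Noisy EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing auditory-oddball event-related potentials in
    noisy, high-density paediatric EEG. Implements channel-by-epoch artifact
    rejection (amplitude threshold and trend-line criteria, with a traditional
    whole-epoch comparator and kurtosis channel screening), robust features
    built from pooled median waveforms (sum of signed differences, partitioned
    variance, and modified multiscale entropy), ICA-based eye-blink component
    scoring, removal and counting, and class-weighted classification under
    leave-one-out cross-validation with nested hyperparameter selection and
    permutation significance testing. A seeded synthetic oddball-EEG cohort
    generator provides ground-truth fixtures for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    glmnet,
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
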
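Package: eegscreen
Title: EEG Wavelet-Feature Pipeline for Dyslexia Screening
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating EEG-based dyslexia screening
    classifiers from task-evoked multichannel recordings. Implements EDF
    reading/writing with a fixed 16-channel 10-20 montage, zero-phase
    Butterworth band-pass and moving-average smoothing, seeded FastICA
    artifact removal with automated ocular/EMG component criteria,
    non-overlapping 10-second epoching, periodized Daubechies-4 level-6
    discrete wavelet decomposition with configurable coefficient-to-band
    mapping, ten statistical descriptors per band and channel, mRMR and
    ReliefF feature ranking, shallow/deep feed-forward classifiers and
    classical baselines under stratified 10-fold cross-validation,
    effect-size/FDR feature screening, and a deterministic synthetic
    task-evoked EEG cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    glmnet,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
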
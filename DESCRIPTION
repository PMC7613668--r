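Package: lfpdetect
Title: Resource-Constrained Seizure-State Classifiers for Local Field
    Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements and evaluates two resource-constrained seizure-state
    classifiers for single-channel local field potential (LFP) signals: a
    classical fixed-point band-power filter chain (Butterworth band-pass,
    Direct Form I with 16-bit coefficients and 32-bit accumulators,
    exponential-moving-average envelope, threshold) and a compact multi-layer
    perceptron with optional convolutional front end, 8-bit post-training
    quantization, and a consensus-of-three adjusted output. Includes a
    synthetic LFP generator (pink-noise background with spike-wave or
    narrowband epileptiform bursts and interval annotations), a training
    pipeline (windowing, 3:1 class rebalancing, 70:30 stratified split,
    binary cross-entropy gradient descent, hyperparameter grid search), and
    an evaluation battery (ROC curves, onset-latency and label-overlap
    statistics, frequency-amplitude response maps), plus EDF/CSV input and
    output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
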
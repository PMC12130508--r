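Package: airsig
Title: Dimension-Wise Shapley Value Feature Selection for In-Air Signature
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for closed-set identification of in-air signatures captured
    as 9-channel inertial time series (accelerometer, gyroscope and attitude,
    x/y/z each). Provides a seeded synthetic corpus generator with
    controllable per-channel informativeness, per-signature CSV input/output,
    length standardisation and subject-stratified splitting, dynamic time
    warping with cost matrix and warping path, time/frequency/complexity
    descriptors, seven 1-D time-series neural-network classifiers (MLP,
    Time-CNN, MC-DCNN, Encoder, FCN, ResNet, InceptionTime) with a
    deterministic training harness, exhaustive channel-coalition experiments
    with exact Shapley value attribution and compatibility curves, and class
    activation maps for the global-average-pooling architectures. A thin
    command-line interface wires the stages into reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
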
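Package: gaitphase
Title: Gait Phase Recognition from Thigh and Knee Signals with Logistic Model Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sliding-window gait phase recognition for wearable stance-control
    orthosis applications. Provides a seeded simulator of labeled knee-angle and
    thigh inertial signals across surfaces and walking speeds, signal
    conditioning (zero-phase Butterworth filtering, linear resampling, resultant
    signals, event-based phase labeling), extraction of a 20-feature vector from
    0.1-s sliding windows, a from-scratch Logistic Model Tree classifier
    (information-gain splits with LogitBoost logistic leaves and cost-complexity
    pruning), a Transition Sequence Verification and Correction (TSVC)
    post-classifier that enforces the cyclic phase order, and multi-class
    evaluation with stratified cross-validation, weighted metrics, and Matthews
    correlation coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
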
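Package: harwear
Title: Human Activity Recognition from Body-Worn Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A portable implementation of a wearable-sensor activity
    recognition pipeline: a unified session data model for multi-device
    inertial recordings (plain-text logs and JSON documents), sampling-rate
    adjustment, non-overlapping sliding-window segmentation in batch and
    streaming modes, per-window time-domain features (mean, variance,
    standard deviation, zero- and mean-crossing rates, extrema), baseline
    and tree classifiers, confusion-matrix metrics (sensitivity,
    specificity, predictive values, F-score), repeated stratified k-fold
    cross-validation, a delay-aligned online evaluation protocol, and a
    seeded generator of realistic multi-subject labelled sessions for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    rpart,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
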
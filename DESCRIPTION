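Package: trampohar
Title: Trampoline Motion Recognition from Smartwatch Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies trampoline exercise motions (standing, walking,
    marching, two-leg and one-leg jumps) from 3-axis wrist accelerometer
    streams sampled at 100 Hz. Provides fixed-window segmentation, a
    VGG-derived 1D convolutional network with a global-average-pooling
    head (implemented in single-precision C++ with Adam training),
    hand-crafted time/frequency feature extraction with a random-forest
    baseline, leave-one-subject-out cross-validation, confusion-matrix
    metrics, label-merging analysis, and on-device-style personalization
    schemes (fine-tuning, classifier-only fine-tuning, mixed retraining).
    Includes a seeded multi-subject synthetic signal generator so the
    full pipeline can be exercised and tested without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    randomForest,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
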
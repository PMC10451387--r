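Package: ictsib
Title: Stability Index Estimation from Center-of-Pressure Sway During the
    Instrumented CTSIB
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for instrumented Clinical Test of Sensory Interaction with
    Balance (i-CTSIB) assessment from center-of-pressure (CoP) recordings.
    Extracts CoP trajectories from pressure-grid mats and four-corner
    load-cell force plates, applies zero-phase Butterworth bandpass
    preprocessing, computes ten standard posturographic sway features
    (time-domain magnitudes, the 95% confidence sway ellipse, and Welch
    spectral percentile frequencies), and fits per-condition regression
    models (ridge, SVM, GAM, regression tree) with Bayesian hyperparameter
    optimization to predict a Biodex-style stability index (SI). Includes a
    calibrated synthetic sway generator and dual-device emulation so the
    whole pipeline is exercisable and testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    lhs,
    e1071,
    mgcv,
    rpart,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    optparse
Config/testthat/edition: 3
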
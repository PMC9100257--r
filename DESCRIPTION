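Package: insoleCG
Title: Center-of-Gravity Trajectory Estimation from Plantar-Pressure Insoles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating the three-axis whole-body center-of-gravity
    (CG) trajectory during gait from an 18-channel (2 x 9 sensor) plantar
    pressure insole system. Implements the full protocol: piezo-resistive
    sensor calibration (exponential voltage-to-force law), zero-phase
    Butterworth filtering, gait-cycle extraction and 100-frame time
    normalization, derivation of 30 per-frame insole parameters including
    zone sums and center of pressure, four-phase gait segmentation with an
    SVM phase classifier, mutual-information feature ranking with per-phase
    feature-count optimization, time-domain data augmentation (jittering,
    time-warping, pooling), and a phase-branched bi-directional LSTM
    regression network trained with Adam, learning-rate-on-plateau and
    early-stopping callbacks. Includes a synthetic gait generator emulating
    young and elderly walking for end-to-end validation, comparative
    feature-selection baselines (RFE, MI, elastic net, no selection), and
    trajectory evaluation metrics (correlation, RMSE, relative RMSE,
    peak-to-valley range group analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    glmnet,
    jsonlite,
    yaml,
    minpack.lm,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
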
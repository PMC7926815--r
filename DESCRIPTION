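Package: gaitgrf
Title: Indirect Estimation of Vertical Ground Reaction Force and Gait
    Parameters from Torso-Mounted Inertial Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating vertical ground reaction force (vGRF),
    ground contact time, and related per-stride gait parameters from a single
    torso-mounted INS/GPS sensor stream, using instrumented-insole force
    recordings as the training reference. Includes a synthetic walk-run gait
    simulator with full ground truth (double-peak walking and single-peak
    running force profiles, double support and flight phases, insole swing
    artifacts), jump-based clock synchronization, stride segmentation,
    per-stride feature and target extraction, two-stage correlation-based
    feature selection, bagged regression-tree parameter models with
    body-weight normalization, K-nearest-neighbor force-curve synthesis in
    time-parameter space, and a sequence-to-point LSTM regressor for
    per-sample vGRF and contact-label prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    rpart,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
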
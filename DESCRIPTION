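Package: gazesim
Title: Binocular Gaze Simulation and Eye-Tracker Calibration Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates binocular gaze vectors for head-mounted eye trackers
    looking at configurable calibration target patterns, corrupts them with
    controlled measurement noise (gaze-direction-dependent systematic error,
    Gaussian precision noise and burst-like false pupil detections), fits
    gaze-mapping functions with five regression families (polynomial least
    squares, lasso, ridge, RANSAC and support vector regression) over their
    hyperparameter grids, and quantifies angular accuracy of the resulting
    calibrations inside and outside the calibrated area.  Includes the full
    repeated-simulation experiment protocol with person-specific kappa-angle
    sampling, file-based configuration, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    glmnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
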
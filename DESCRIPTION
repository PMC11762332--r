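Package: drivecog
Title: Turn-Maneuver Driving Biomarkers for Cognitive Impairment Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates standardized driving-assessment sessions (multirate
    gyroscope/accelerometer at 10 Hz and GPS at 1 Hz over a fixed 540 m
    circuit), detects turning maneuvers from the yaw-rate channel, extracts a
    26-feature kinematic representation per subject (turn angular velocity,
    windowed discrete-derivative angular acceleration, turn speed, U-turn
    duration, under normal and aggressive driving), and classifies subjects as
    healthy or mildly cognitively impaired under leakage-free inter-subject
    cross-validation with per-fold standardization and PCA. Original features
    are ranked by a variance-weighted absolute-loading contribution metric
    aggregated across folds. Includes diagnostic metrics (sensitivity,
    specificity, PPV, NPV), an end-to-end pipeline, and plain-text reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    class,
    rpart,
    e1071,
    randomForest,
    glmnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
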
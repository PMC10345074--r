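Package: circdip
Title: Circadian Heart Rate Profiling and Nocturnal Dipping Analysis for
    Stroke Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for circadian profiling of heart rate and heart rate
    variability from beat-to-beat ECG annotations recorded on stroke units.
    Converts timestamped RR-interval series into 5-minute segment metrics
    (heart rate, SDNN, RMSSD, LF and HF spectral power), builds hour-of-day
    circadian profiles, quantifies nocturnal heart-rate dipping, and relates
    dipping to dichotomized functional outcome (modified Rankin Scale) via
    per-hour group tests, propensity-score matching on age and stroke
    severity, and nested cross-validated outcome prediction with and without
    the nocturnal heart-rate feature. Includes a synthetic cohort generator
    that emulates circadian HR modulation, LF/HF band oscillations, beat-label
    noise, recording gaps, atrial-fibrillation-like series and covariate
    imbalance, so the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    xgboost,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
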
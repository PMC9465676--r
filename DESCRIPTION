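Package: vo2wear
Title: Instantaneous Oxygen Uptake Estimation from Wearable Cardiorespiratory Signals
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing and machine-learning pipeline for estimating
    instantaneous oxygen uptake (VO2, ml/kg/min) from a wearable vest recording
    single-lead ECG (200 Hz), thoracic and abdominal respiration (25 Hz) and
    tri-axial acceleration (25 Hz). Provides filtering chains for each channel,
    Hamilton-style R-peak detection, respiratory peak/trough detection, motion
    intensity features (signal vector magnitude and its mean absolute
    differential), assembly of a synchronized 1 Hz feature frame, gradient-boosted
    regression with grid-searched hyperparameters, leave-one-subject-out and
    gender-crossover evaluation with Bland-Altman agreement statistics, and a
    protocol simulator (posture battery, treadmill warm-up, Bruce incremental
    stages, recovery) that generates coupled synthetic cohorts with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'vo2wear-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'dwt.R'
    'filters.R'
    'io-delimited.R'
    'io-edf.R'
    'slice.R'
    'detect-rpeaks.R'
    'detect-breaths.R'
    'hr.R'
    'motion.R'
    'resample.R'
    'feature-frame.R'
    'feature-sets.R'
    'metrics.R'
    'model.R'
    'evaluate.R'
    'simulate.R'
    'config.R'
    'cli.R'
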
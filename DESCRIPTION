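Package: soleGRF
Title: Ground Reaction Force Prediction from Instrumented Shoe-Sole Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end analysis pipeline for predicting three-directional
    ground reaction forces (GRFs) from a four-site triaxial shoe-sole sensor
    system. Provides a seeded synthetic gait generator emulating multi-rate
    sensor, force-plate and marker recordings for straight walking and
    side-/cross-step turns; signal preprocessing (zero-phase Butterworth
    filtering, force-threshold stance detection, heading-angle rotation into
    the shoe frame, 101-point stance normalization); stepwise multiple linear
    regression; exact Gaussian process regression with a squared-exponential
    kernel, constant basis and marginal-likelihood hyperparameter fitting;
    and leave-one-step-out cross-validation with MAE, percent RMSE and
    adjusted R-squared summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'evaluation.R'
    'gpr.R'
    'io.R'
    'mlr.R'
    'pipeline.R'
    'preprocess.R'
    'soleGRF-package.R'
    'synthetic.R'
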
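Package: gprload
Title: Continuous Mental Workload Estimation from EEG Band Power with
    Gaussian Process Regression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates N-back working-memory sessions and synthetic
    multi-channel EEG epochs with a known ground-truth mapping from task
    load to spectral band power, extracts normalized log band-power
    features via Welch spectral estimation, and estimates task load as a
    continuous variable with exact Gaussian process regression using a
    squared-exponential covariance with automatic relevance determination
    (ARD). Includes a multiple linear regression baseline, Haufe-style
    activation patterns, per-feature one-way ANOVA ranking, blocked
    cross-validation with a temporal leakage buffer, feature-subset and
    electrode-montage evaluations, and cross-task-variant transfer
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    withr,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'montage.R'
    'AllClasses.R'
    'AllGenerics.R'
    'nback.R'
    'synthesizer.R'
    'features.R'
    'gpr.R'
    'baselines.R'
    'evaluation.R'
    'pipeline.R'
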
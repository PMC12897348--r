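Package: osascreen
Title: Wakefulness-Based Obstructive Sleep Apnea Severity Screening from
    Tracheal Breathing Sounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for multi-class obstructive sleep apnea (OSA) severity
    screening from tracheal breathing sounds recorded during wakefulness.
    Provides a synthetic cohort generator (audio plus anthropometrics),
    breath-phase segmentation and denoising, a versioned acoustic feature
    dictionary (spectral, higher-order spectral, time-domain, wavelet and
    constant-Q, nonlinear dynamics, and perturbation families), stratified
    k-NN imputation with mutual-information-guided adaptive normalization,
    a three-stage feature-selection pipeline, six one-vs-one bagged base
    classifiers with out-of-bag validation, a stacked meta-model for
    three- and four-class severity schemes, and split conformal prediction
    sets with finite-sample coverage guarantees, together with joint
    stratified partitioning and paired classifier-comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    e1071,
    ranger,
    nnet,
    rpart,
    xgboost,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
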
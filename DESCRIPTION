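Package: stemiscreen
Title: Prehospital STEMI Screening with a Bagged Neural-Network ECG Ensemble
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for screening prehospital 12-lead ECGs for
    ST-elevation myocardial infarction (STEMI) and the need of acute
    percutaneous coronary intervention. Provides a seeded synthetic ECG
    cohort generator with controllable ST elevation, fiducial-point
    detection and extraction of 13 amplitude/duration measurements per lead
    (156 variables per record), train-set-fitted principal-component
    reduction to 20 Z-scored inputs, an ensemble of 25 bagged
    single-hidden-layer perceptrons trained with a cross-entropy loss plus
    a weight-elimination penalty, and diagnostic-test evaluation: ROC and
    AUROC with bootstrap intervals, sensitivity-anchored operating points,
    exact Clopper-Pearson intervals, serial combination with a confirmatory
    reader, and transmission-reduction analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
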
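Package: gaitprog
Title: Prognosis of Post-Stroke Ambulation Level from Admission Wearable IMU Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for predicting household versus community ambulation at
    inpatient-rehabilitation discharge from data available at admission:
    patient information, functional-assessment scores, and features computed
    from three body-worn inertial measurement units (pelvis and bilateral
    ankles) recorded during a short walking bout. Provides a synthetic-cohort
    generator with class-dependent gait-signal structure, magnitude-based IMU
    feature extraction (amount of motion, sample entropy, summary statistics)
    under fixed-distance and fixed-duration walking paradigms, a balanced
    random forest for the imbalanced two-class problem, seed-averaged
    recursive-feature-elimination importance aggregation with backward
    elimination, majority-vote randomized hyperparameter search, and
    leave-one-subject-out evaluation with weighted F1, accuracy, AUROC, and
    admission-to-discharge transition-group analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ranger,
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
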
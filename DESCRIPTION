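Package: unidiag
Title: Unifying Diagnosis Identification and Prediction from Coded
    Diagnostic Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies and predicts a unifying diagnosis (the minimal set
    of primary diseases separated from complications) from multi-code
    patient diagnostic records. Reconstructs the five-level ICD-9-CM
    ontology and measures ontology-embedded semantic similarity between
    diagnosis codes (least-common-ancestor information content) and
    between patients' diagnosis-code sets; clusters patients by affinity
    propagation with a median-preference rule; extracts typical
    diagnosis-code co-occurrence patterns from cluster core zones; groups
    typical codes under least common ancestors and splits primary diseases
    from complications via a conditional co-occurrence matrix; and trains
    multi-class classifiers on fused admission features (demographics,
    text-derived symptom flags, laboratory five-tuples, severity scores)
    with information-gain feature selection under stratified cross-
    validation. Includes a seeded synthetic cohort generator with known
    group structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pROC,
    nnet,
    rpart,
    randomForest,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
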
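Package: mesopanel
Title: Serum Proteomic Panel Discovery and Blinded Evaluation for
    Mesothelioma Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for affinity-proteomic
    (aptamer/SOMAmer-style) biomarker panel development in case-control
    serum studies of malignant pleural mesothelioma. Covers relative
    fluorescence unit (RFU) matrix input/output with strict validation,
    median normalization and calibrator-based inter-plate scaling,
    preanalytic-variability quality control (Kolmogorov-Smirnov control-set
    screening, paired pre-operative/intra-operative draw filtering, and
    PCA artifact detection), univariate candidate selection with
    Benjamini-Hochberg control, random-forest Gini-importance panel
    ranking with a panel-size scan, fixed-threshold random-forest
    classification with blinded scoring, assay-version bridging, and the
    full set of diagnostic evaluation statistics (Wald confidence
    intervals, ROC/AUC with DeLong or bootstrap intervals, stage-stratified
    sensitivity, and prevalence-adjusted screening estimates). Includes a
    synthetic cohort generator that emulates the statistical structure of
    a multi-center serum study so the whole pipeline is testable without
    access to proprietary assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
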
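Package: melaprog
Title: Whole-Slide-Image Prognosis of 1-Year Disease-Free Survival in Cutaneous Melanoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for predicting 1-year disease-free survival in
    stage I-III cutaneous melanoma from annotated whole-slide images. Provides
    ROI tessellation into 224x224 tiles, Laplacian-of-Gaussian cell detection,
    90th-percentile cell-density tile filtering, Gaussian crop sampling with a
    Luma background filter, Macenko stain normalization, pluggable
    transfer-learning feature backends, a nested waterfall (AUC filter + PCA)
    feature selector feeding an RBF-SVM crop classifier, 75th-percentile
    vote-score aggregation to slide level, a three-model ensemble with a
    clinical-covariate SVM and soft voting, and a patient-stratified 5x5
    cross-validation harness with Youden-index thresholding and imbalance-aware
    metrics. Includes a synthetic histology cohort generator (Beer-Lambert
    two-stain color formation, elliptical nuclei, plantable class signal) so
    the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
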
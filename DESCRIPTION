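Package: rimshrink
Title: CT Radiomics with Millimetre-Calibrated ROI Erosion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the partial-volume effect in CT radiomics of
    adrenal lesions. Derives four region-of-interest variants from a lesion
    mask (maximum-area slice and full volume, each optionally eroded inward
    by a millimetre-calibrated radius), extracts a 104-feature radiomics
    vector (first-order, 3D shape, and grey-level texture matrices) after
    windowing, nearest-neighbour resampling and fixed-bin-width
    discretization, screens features by inter-rater intraclass correlation,
    runs a univariate, recursive-feature-elimination and LASSO selection
    cascade, fits a logistic radiomics signature, and compares the ROI
    methods by AUC, partial AUC at high specificity, McNemar and pairwise
    score tests, and decision-curve analysis. Includes a synthetic CT
    phantom generator with point-spread blur, correlated lesion texture and
    a simulated second rater for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
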
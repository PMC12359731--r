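Package: periradiomics
Title: Intratumoral and Peritumoral CT Radiomics for Predicting Lung
    Nodule Invasiveness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for CT-radiomics analysis of subcentimeter
    lung adenocarcinoma invasiveness (minimally invasive versus invasive
    adenocarcinoma). Builds intratumoral and peritumoral regions of
    interest by spacing-aware Euclidean dilation of the gross tumor
    volume, extracts first-order, shape, and five gray-level texture
    feature families from discretized Hounsfield intensities, reduces
    features by an intraclass-correlation stability filter, minimum
    redundancy maximum relevance ranking, and cross-validated LASSO
    logistic regression into a radiomics score, and evaluates logistic
    predictive models with ROC/DeLong comparisons, bootstrap confidence
    intervals, Hosmer-Lemeshow calibration, and decision-curve analysis.
    A synthetic three-dimensional nodule cohort generator provides
    reproducible test beds matching the clinical covariate structure of a
    published subcentimeter adenocarcinoma cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    RNifti,
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
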
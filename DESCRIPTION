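Package: radiotme
Title: Intratumoral and Peritumoral MRI Radiomics for Tumor-Microenvironment Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiomics pipeline for predicting tumor-microenvironment components
    (extracellular-matrix proteins and immune-cell densities) from multiparametric
    breast MRI. Builds intratumoral and peritumoral regions by physical-distance
    dilation on an isotropic grid, extracts a countable 1618-feature registry
    (first-order, shape, GLCM/GLRLM texture, and undecimated Haar wavelet
    sub-band features) per region and sequence, discovers linear radiomic
    signatures by iterated LASSO stability selection, and evaluates them with
    ROC/AUC, percentile-bootstrap confidence intervals, DeLong comparisons with
    Bonferroni correction, cross-validated AUCs, decision-curve analysis and
    subtype-stratified bootstrap tests. Includes a synthetic multiparametric
    cohort generator with planted, analytically controlled effect sizes so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
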
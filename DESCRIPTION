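Package: habitatct
Title: Habitat Radiomics for CT Tumor Subregion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for habitat radiomics on CT: voxel-level local texture
    feature maps inside a tumor region of interest, k-means partitioning of
    the tumor into texture-defined habitats, whole-tumor and per-habitat
    radiomic feature extraction (first-order, shape, GLCM, GLRLM, GLSZM,
    NGTDM, GLDM), a reproducibility/univariate/redundancy/LASSO feature
    selection cascade, a five-learner by eight-feature-set model grid with
    average-AUC model selection, and evaluation by ROC/AUC, DeLong tests,
    calibration curves and decision-curve analysis. Includes a synthetic
    cohort generator that plants habitat structure, clinical covariates and
    a logistic label model so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    e1071,
    nnet,
    RNifti,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
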
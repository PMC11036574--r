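Package: radimmune
Title: CT Radiomics Signatures for Chemoradiotherapy-Induced Changes in
    Tumor-Infiltrating Immune Cells
Version: 0.1.0
Authors@R:
    person("radimmune", "maintainers", email = "maintainers@radimmune.dev",
           role = c("aut", "cre"))
Description: Tools to reproduce a two-stage tumor-immune analysis for cervical
    cancer under concurrent chemoradiotherapy: an immunomarker classifier
    scoring treatment-induced changes in tumor-infiltrating CD8+ T cells and
    CD68+ macrophages, and a CT radiomics signature (97-feature bank of
    first-order, shape and GLCM/GLRLM/GLSZM texture features; univariate
    screening at p < 0.2; LASSO-penalized logistic regression with stratified
    ten-fold cross-validation) that predicts the immune class from pre-treatment
    CT. Includes ROC/Youden cutoff stratification, contingency-table
    association statistics, hematological ratio dichotomization, a minimal
    NIfTI-1 volume reader/writer, and a seedable synthetic-cohort generator
    (volumes, masks and clinical tables) for end-to-end testing without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
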
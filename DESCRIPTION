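Package: trmspatial
Title: Spatial Phenotyping and Prognostic Signatures for Tissue-Resident
    Memory T Cells in Multiplex Immunofluorescence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the spatial organisation of
    CD103+CD8+ tissue-resident memory T (TRM) cell subsets in per-cell
    tables exported from multiplex immunofluorescence image analysis.
    Computes four per-patient spatial immune features (cell density per
    1000 cells, epithelium/stroma infiltration score, mean nearest
    neighbour distance to cancer cells, and cancer-cell proximity
    score), builds a TRM-based spatial immune signature by intersecting
    penalized Cox, gradient-boosting and random survival forest feature
    importances with maximally selected log-rank cut-points, and
    evaluates it with Kaplan-Meier, Cox regression and time-dependent
    ROC analysis. Includes a seeded synthetic cohort generator with
    planted spatial effects and survival outcomes so every stage of the
    pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    ranger,
    stats,
    survival,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
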
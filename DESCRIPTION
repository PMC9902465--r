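Package: fcfusion
Title: Multi-Measure Resting-State fMRI Connectivity, Classification and
    Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes voxel-wise resting-state fMRI activity measures (ALFF,
    fALFF, ReHo) and six ROI-wise functional-connectivity estimators --
    Pearson correlation, topographical and dynamics-based high-order
    connectivity, and four sparse-representation network estimators (SR,
    SLR, GSR, SSGSR) -- and evaluates their discriminative power with a
    Boruta-style shadow-feature selector inside nested cross-validation,
    multi-modal fusion by feature concatenation and multiple kernel
    learning, and group-level biomarker identification with FDR and
    permutation cluster-extent correction. Includes a seeded synthetic
    two-group cohort generator with planted connectivity and voxel effects
    so the full pipeline is testable without access to restricted cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    e1071,
    ranger,
    xgboost,
    rpart,
    class,
    glmnet,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
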
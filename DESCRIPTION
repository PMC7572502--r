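Package: metabostate
Title: Health-State Prediction from Untargeted Metabolomics Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for case/control classification from
    untargeted LC/GC-MS feature tables (mass-to-charge ratio, retention
    time, intensity triplets). Implements intensity flooring and binary log
    transformation, per-batch percentile normalization against controls,
    Mann-Whitney U testing with Benjamini-Hochberg FDR correction computed
    inside the training loop to avoid selection leakage, feature regimes
    (all, significant-only, top-k, non-significant-only, non-significant
    with adduct/isotope satellites removed), mass-difference/retention-time
    annotation of putative adducts and isotopes, and stratified nested
    cross-validated evaluation of L1-regularized logistic regression over
    repeated data shuffles. A synthetic-data generator with planted markers,
    correlated satellite features, diffuse weak signal and batch effects
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0), pROC, optparse
Config/testthat/edition: 3
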
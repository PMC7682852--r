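Package: twoStepOmics
Title: Two-Step Multi-Omics Classification of Drug Sensitivity in Cancer
    Cell Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Late-integration modelling of pharmacogenomic screens.
    Single-data-type first-step models (cluster predictors on somatic
    mutation, copy-number, hypermethylation and tissue descriptors;
    principal-component and pathway-activity regressions on continuous
    data) are trained per cross-validation fold and their outputs are
    integrated by a registry of thirteen classification algorithms.
    Exhaustive ablation studies quantify the contribution and redundancy
    of each data type, and cross-fold stability reporting surfaces
    candidate biomarkers of drug sensitivity. A seeded synthetic-data
    generator with planted driver features supports end-to-end testing
    without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    withr,
    e1071,
    nnet,
    randomForest,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
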
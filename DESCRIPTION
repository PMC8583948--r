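Package: integromics
Title: Consensus Multi-Omics Integration for Small Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential-abundance screening and statistical integration of
    paired proteomic and metabolomic feature tables from small case-control
    cohorts. Implements a per-layer screen (missingness filter, per-group
    Dixon outlier removal, Mann-Whitney U tests with Benjamini-Hochberg
    correction, log2 fold changes), merging of significant features across
    layers with train/test partitioning, scaling and K-nearest-neighbour
    imputation learned on the training set, dual-algorithm feature selection
    (recursive feature elimination and minimal-redundancy-maximal-relevance
    ranking over elastic-net logistic regression), a 2-of-3 consensus rule
    for the final biomarker panel, and held-out confusion-matrix evaluation.
    Ships a synthetic cohort generator with planted effects for end-to-end
    validation, and a pathway-coverage summary for externally supplied
    pathway membership lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'OmicsLayer.R'
    'consensus.R'
    'differential.R'
    'dixon.R'
    'elastic-net.R'
    'integrate.R'
    'pathways.R'
    'select.R'
    'synthetic.R'
    'utils.R'
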
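Package: stabsig
Title: Stability-Selected Predictive Gene Signatures from Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives responder/nonresponder gene signatures from bulk
    whole-blood RNA-seq cohorts with clinical outcomes and builds a
    predictive gene signature by bootstrap-stabilized elastic-net logistic
    regression. Provides median-of-ratios count normalization, expression
    filtering, Wilcoxon rank-sum marker signatures, Pearson
    correlation-based signature derivation with placebo exclusion and
    cross-study intersection, expression-bin-matched module scores,
    repeated-partition bootstrap stability selection with cross-validated
    elastic-net fits, a weighted-sum response score, and subsampled ROC
    validation with Youden's J thresholds. A negative-binomial two-study
    cohort simulator with planted signal genes supplies ground-truth test
    beds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    glmnet,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Collate: 
    'stabsig-package.R'
    'AllClasses.R'
    'correlation.R'
    'io.R'
    'module_score.R'
    'pipeline.R'
    'preprocess.R'
    'simulate.R'
    'stability.R'
    'validation.R'
    'wilcoxon.R'
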
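Package: mastsig
Title: Minimal Cytokine-Activated Mast-Cell Gene Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives minimal cytokine-activated gene signatures from a paired
    multi-condition mast-cell priming experiment and applies them to detect
    cytokine priming in bulk, pseudobulk and single-cell expression data.
    Provides negative-binomial Wald differential expression with
    median-of-ratios normalization, Venn partitioning of differentially
    expressed genes into condition-unique and shared sets, multinomial
    elastic-net feature selection with exact classifier evaluation statistics,
    a gene set variation analysis (GSVA) enrichment engine with moderated
    (empirical-Bayes) group comparisons, per-cell signature scoring, pseudotime
    phase analytics with Fisher trajectory-utilization tests, cohort z-score
    signature statistics, and synthetic data generators that emulate the
    statistical structure of each experiment for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    glmnet,
    limma,
    methods,
    nnet,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
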
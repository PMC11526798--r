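Package: stagewiseDE
Title: Stage-Salient Biomarker Discovery from Stage-Annotated Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and evaluation of discrete-stage cancer biomarkers from
    stage-annotated bulk expression data. Implements stagewise moderated linear
    models and between-stage contrasts on voom-transformed expression, a
    stage-salience filter built on a product-of-p-values statistic (pval_pdt),
    monotone expression trend detection across ordered stages, intersection
    into progression-significant genes, a small-panel diagnostic classifier
    with a full confusion-matrix metric suite, and a Cox risk-score prognostic
    model with Kaplan-Meier stratification. Ships a synthetic-data generator
    with planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    methods,
    survival,
    randomForest,
    e1071,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
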
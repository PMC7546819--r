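Package: txclock
Title: Transcriptomic Age Prediction from Single and Paired Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds elastic-net chronological-age predictors from bulk gene
    expression. Implements the full model-selection pipeline used for
    multi-tissue transcriptomic clocks: quantile normalization, log2
    transformation, Pearson-correlation gene preselection, a coordinate-descent
    elastic-net solver on the unscaled residual-sum-of-squares objective,
    repeated k-fold cross-validation with fold-internal gene reranking, joint
    grid search over the number of preselected genes and the penalty
    parameters, and combination of two tissues over shared donors with
    per-tissue feature budgets. Ships a seeded multi-tissue cohort simulator
    with known ground truth, GCT 1.2 and TSV readers and writers, and
    command-line entry points.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
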
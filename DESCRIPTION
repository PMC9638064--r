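Package: scmrmr
Title: Marker Panel Discovery for Single-Cell Expression Data via
    mRMR Ranking and Incremental Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers compact gene panels that separate two cell
    populations (e.g. tumor versus adjacent normal cells) in
    single-cell RNA-seq count matrices. Genes are ranked by the
    Max-Relevance Min-Redundancy (mRMR) criterion on mutual
    information over discretized expression, nested top-k panels are
    evaluated with a linear support vector machine under
    leave-one-out cross-validation scored by the Matthews
    correlation coefficient, and the smallest panel attaining the
    peak score is selected and validated on held-out patient
    cohorts. Includes a seeded negative-binomial simulator of
    multi-patient two-class datasets with planted markers and
    redundant co-expressed gene blocks for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Rtsne,
    e1071,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
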
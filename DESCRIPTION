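Package: chronoseq
Title: Dense Time-Course RNA-seq Analysis with Lead-Lag Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for dense time-course bulk RNA-seq experiments:
    negative-binomial count simulation with planted temporal profile classes and
    lead-lag couplings, gene filtering and TMM/log2 normalization, precision-weighted
    spline and per-timepoint differential expression with empirical-Bayes variance
    moderation, hierarchical and autocorrelation-distance profile clustering,
    nonparametric detection of circadian-scale rhythms with an exact Kendall null,
    paired maxmean gene-set scoring with permutation calibration, and sliding-window
    Granger-causality network inference using bivariate least squares and de-biased
    LASSO estimators with sign- and persistence-based edge filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    glmnet,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
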
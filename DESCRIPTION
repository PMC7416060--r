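Package: dynconn
Title: Task-Modulated Dynamic Functional Connectivity via Conditional
    Correlation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Framewise dynamic functional connectivity for blocked task
    designs. Estimates per-frame correlation matrices from multivariate
    region time series with a two-stage quasi-maximum-likelihood dynamic
    conditional correlation (GARCH(1,1) + scalar DCC(1,1)) model, reduces
    them to network-level connection weights and whole-graph topological
    indexes (global efficiency, deterministic modularity, edge-betweenness
    resilience), computes task-modulated variability statistics from
    HRF-convolved condition regressors, and provides the group-level
    inference layer (repeated-measures ANOVA with sphericity handling,
    Spearman partial correlations under a restricted Benjamini-Hochberg
    FDR). Includes a synthetic cohort generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    car,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
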
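Package: growthpool
Title: Life-Course Growth Trajectories from Pooled Heterogeneous Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combining longitudinal anthropometric data from
    heterogeneous cohort studies that cover different and overlapping periods
    of life into a single life-course trajectory model.  Provides data
    harmonization with configurable category mappings and a pooling audit,
    fractional-polynomial and restricted-cubic-spline trajectory bases, a
    two-level linear mixed model estimated by exact block-diagonal maximum
    likelihood or REML with complex (age-dependent) level-1 residual
    variance, two-stage trajectory/covariance model selection with a
    validation-sample mean squared prediction error, an iterative multiple
    imputation procedure for sporadically and systematically missing
    child-level covariates driven by empirical-Bayes trajectory summaries,
    Rubin's-rules pooling, and a synthetic multi-cohort data generator with
    known truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    nnet,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
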
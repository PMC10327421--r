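Package: dsilt
Title: Data-Shielding Integrative Large-Scale Testing for Federated
    High-Dimensional Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simultaneous inference on covariate effects across multiple
    studies whose individual-level data cannot be pooled.  Each study site
    shares only summary statistics (score vectors and Hessian matrices) with
    a central analysis node, which fits a group-lasso integrative estimator,
    debiases it per covariate with a group Dantzig-selector projection, and
    tests the cross-study group effect of every covariate with a chi-square
    statistic.  A normal-quantile transform and a tailored thresholding rule
    control the false discovery rate and proportion over all covariates.
    Includes the One-shot (local debiasing) and individual-level
    meta-analysis comparators, a synthetic federated-data generator for
    logistic and linear outcomes with heterogeneous shared-support
    coefficients, and a replication-study runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
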
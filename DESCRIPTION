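Package: ConnDensity
Title: Connectivity Density Regression for Functional Connectomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Treats each subject's functional-connectivity correlations as
    draws from a subject-specific connection density and relates those
    densities to a binary intervention label by scalar-on-function logistic
    regression.  Densities are estimated on [-1, 1] by penalized log-spline
    maximum likelihood (or Gaussian kernel smoothing), transformed to
    log-density-quantile curves, reduced by functional principal component
    analysis with a smoothed covariance, and entered as covariates in an
    inverse case-control logit model with likelihood-ratio, permutation-AUC
    and Bayesian-band inference.  Includes edgewise and principal-component
    regression baselines, a von Mises connectivity simulator with a
    stimulation perturbation, a positive-finding-rate benchmark harness,
    and stimulation-induced connectivity localization diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    splines,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
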
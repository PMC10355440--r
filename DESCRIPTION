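Package: mvmash
Title: Multivariate Multiple Regression with Adaptive Shrinkage Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits Bayesian multivariate, multiple regression models in which
    the effects of each predictor on several correlated outcomes are given a
    mixture-of-multivariate-normals prior that adapts, by empirical Bayes, to
    the patterns of effect sharing present in the data. Model fitting uses a
    fast coordinate-ascent variational algorithm and handles missing outcome
    entries by integrating their imputation into the fitting loop. Designed
    for predicting multi-tissue gene expression from genotype dosages and,
    more generally, for polygenic prediction of multiple correlated
    phenotypes. Includes constructors for canonical and data-driven prior
    covariance collections, a simulator for multi-condition genotype and
    phenotype data under controlled effect-sharing scenarios, and
    prediction-accuracy metrics.
License: MIT
Encoding: UTF-8
Imports: Rcpp, jsonlite, graphics, stats, utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), glmnet, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
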
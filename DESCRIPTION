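Package: bfr
Title: Bayesian Functional Regression for High-Throughput Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scalar-on-function regression for predicting scalar traits
    (e.g., grain yield) from high-dimensional curve predictors such as
    hyperspectral reflectance bands. Curves are represented with B-spline
    or Fourier basis expansions; regression designs are built either on the
    raw band matrix, on cross-basis integrals, on smoothed curves, or on a
    reduced basis-projected matrix. Coefficients are estimated by Gibbs
    sampling under five shrinkage priors (Bayesian ridge, BayesA, BayesB,
    BayesC and the Bayesian lasso), and predictive accuracy is assessed by
    k-fold cross-validation with Pearson correlation. Includes generators
    for synthetic hyperspectral-like data with known smooth truth, knot
    selection by generalized cross-validation, tidy and autoplot methods,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
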
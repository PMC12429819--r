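Package: ohcasim
Title: Simulation of Missing-Data Handling in OHCA Registry Association Analyses
Version: 0.1.0
Authors@R:
    person("OHCA", "Methods", email = "ohca.methods@example.org", role = c("aut", "cre"))
Description: Tools to study how complete-case analysis and four single-imputation
    methods (mean/mode, missingness-indicator, iterative random-forest, and
    Gower-distance k-nearest-neighbours) affect a multivariable logistic
    association analysis under missing-at-random (MAR) covariate missingness.
    Generates synthetic out-of-hospital cardiac arrest (OHCA) cohorts from
    published stratum counts or from a logistic outcome model with known
    coefficients, introduces MAR missingness by a weighted-score amputation
    mechanism, imputes, refits the association model, and summarises bias,
    empirical standard error and confidence-interval coverage across
    simulation repetitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
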
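Package: rpbivop
Title: Random-Parameters Bivariate Ordered Probit Models for Paired Crash
    Injury Severities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Joint modelling of the ordinal injury severities of the two
    drivers involved in the same rear-end crash.  Implements the bivariate
    ordered probit likelihood built from standard bivariate normal rectangle
    probabilities, a random-parameters (mixed) extension estimated by maximum
    simulated likelihood with scrambled Halton draws, numerical-Hessian
    standard errors with delta-method transforms, and an iterative rule that
    fixes random coefficients whose standard deviations are not significant.
    Includes a synthetic crash-data generator emulating national crash-sample
    extracts (KABCO-derived four-level outcomes, dummy-coded covariates shared
    within a crash or specific to a driver), CSV/YAML input handling, and
    tabular reporting of estimates, z values and percent observations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
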
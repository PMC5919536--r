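Package: rhdtiter
Title: Anti-RhD Titer Dynamics in Hyper-Immunised Plasma Donors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models longitudinal anti-RhD antibody titers of hyper-immunised
    plasma donors as a donor-specific log-linear decline combined with a
    logistically saturating response to booster immunisations.  Provides the
    staged estimation pipeline (random-effects decline fit, booster-timing and
    booster-magnitude nonlinear least squares, and an integral nonlinear
    mixed-effects fit with iterated latent starting titers), empirical-Bayes
    and MAP donor-level parameter estimation, steady-state analysis of
    fixed-interval boostering regimes, a synthetic donor-cohort generator for
    validation studies, and readers/writers for the anonymised and
    day-resolved longitudinal CSV formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
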
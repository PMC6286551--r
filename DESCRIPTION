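Package: coxladder
Title: Prognostic Cox Models of Increasing Complexity for Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares prognostic Cox proportional-hazards models of
    successively increasing complexity -- dichotomized predictors,
    predictors categorized into three or four groups, fractional-polynomial
    (FP) transformed predictors selected by a closed-test procedure (MFP),
    and restricted-cubic-spline (RCS) transformed predictors -- on
    breast-cancer-like survival cohorts. Provides from-scratch stratified
    Cox partial-likelihood estimation with Breslow and Efron tie handling,
    Kaplan-Meier estimation with Greenwood variance, Schoenfeld
    proportional-hazards checking, Harrell's concordance index, prognostic
    index risk grouping at fixed percentiles, bootstrap percentile bands
    for relative-hazard curves, derivation-to-validation weight transport,
    and a synthetic cohort generator with known true covariate effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
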
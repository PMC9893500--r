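Package: circatherm
Title: Circadian Core Body Temperature Phenotypes, Feed Efficiency, and
    Genetic Parameters for Beef Cattle in Winter Feeding Regimes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning high-frequency reticulo-rumen and rectal
    temperature telemetry from beef steers into circadian rhythm phenotypes
    (MESOR, amplitude, acrophase) via single-component 24-h cosinor fits,
    for computing residual-based production efficiency indices (residual
    feed intake, residual body gain, residual intake and gain), and for
    estimating heritabilities and genetic/phenotypic correlations across
    two winter feeding regimes with a Bayesian bivariate pedigree animal
    model fitted by Gibbs sampling. Includes telemetry cleaning (physiological
    range filter, autoregressive drinking-bout artifact detection,
    completeness checks), diet energy and temperature-humidity index
    calculations, within-animal partial correlations, and a synthetic-data
    generator that emulates the structure of a two-year, two-regime steer
    backgrounding trial for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    emmeans
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
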
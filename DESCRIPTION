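Package: airmes
Title: Simulating the Impact of Exposure Measurement Error on Air
    Pollution Health Effect Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation framework for quantifying how measurement error in
    modeled ambient particulate-matter exposures biases health effect
    estimates from a multilevel Poisson model that estimates short- and
    long-term effects simultaneously. Simulates a "true" daily concentration
    surface over a set of small spatial units with explicit spatial
    covariance (fitted exponential semivariogram) and temporal
    autocorrelation, degrades it into method-specific "modeled" exposures
    characterized by spatial/temporal correlation coefficients and variance
    ratios against the truth, simulates daily counts under a Poisson
    random-intercept model, refits on the error-laden exposures, and reports
    percent bias, empirical SD, mean standard error, coverage and power over
    replicated scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
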
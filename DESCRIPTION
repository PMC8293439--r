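Package: potsim
Title: Process Overlap Theory Simulation and Latent-Variable Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cognitive test batteries under process overlap theory
    (POT), in which every test item samples an overlapping set of
    domain-general executive attention processes and domain-specific
    processes, and item responses follow a non-compensatory two-factor
    logistic item response model. Provides a maximum-likelihood structural
    equation engine for higher-order confirmatory factor models with
    standard fit indices (chi-square, CFI, RMSEA with 90% confidence
    interval, SRMR), regression-method factor scores, commonality analysis
    of unique and shared criterion variance across three predictors, and a
    Monte-Carlo driver that replicates full simulation studies and fits
    executive-function structural models to user-supplied correlation
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
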
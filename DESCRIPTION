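Package: bayesdr
Title: Approximate Bayesian Doubly Robust Estimation of Average Treatment Effects
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Doubly robust (DR) estimation of average treatment effects for
    binary treatments, with approximate Bayesian posteriors obtained by solving
    inverse-propensity-weighted estimating equations under Dirichlet (Bayesian
    bootstrap) observation weights, and prior information incorporated through
    the Muliere-Secchi mixture resampling scheme. Provides outcome-regression,
    inverse-propensity-weighted and DR point estimators, nearest-neighbour
    propensity score matching, a Monte Carlo misspecification study of the
    estimators, and a synthetic generator of before/after road-safety site
    panels for end-to-end pipeline validation with a known embedded effect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
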
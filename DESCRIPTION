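Package: ceamiss
Title: Bayesian Cost-Effectiveness Analysis with Missing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fully Bayesian cost-effectiveness analysis of two-arm
    trials in which quality-of-life scores, costs or baseline covariates are
    incompletely observed.  Implements a joint pattern-mixture model (an
    arm-specific multivariate-normal imputation model for repeated
    quality-of-life scores linked to a bivariate QALY/cost substantive model)
    with missing-not-at-random sensitivity parameters, priors for those
    parameters built by linear opinion pooling of expert-elicited bivariate
    normal beliefs, a Gibbs sampler with data augmentation for the missing
    values, Gelman-Rubin convergence diagnostics, and decision outputs
    (incremental net benefit, probability cost-effective, cost-effectiveness
    acceptability curves, density strips and tipping-point scans).  A
    synthetic-trial generator with known pattern-mixture offsets supports
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mvtnorm,
    stats,
    utils
Suggests:
    coda,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
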
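Package: ssdbayes
Title: Bayesian, Mixed Bayesian-Likelihood and Frequentist Sample Size
    Determination for Means and Proportions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sample size determination (SSD) for estimating a population
    mean of a normally distributed variable and a population proportion
    (areal fraction) under precision requirements on the length or
    coverage of interval estimates.  Implements the fully Bayesian and
    mixed Bayesian-likelihood approaches with conjugate normal-gamma and
    beta priors under the average length (ALC), average coverage (ACC)
    and modified worst outcome (WOC) criteria, alongside the classical
    frequentist closed forms (normal approximation and Wald interval).
    Includes highest-posterior-density interval numerics for scaled-t and
    beta posteriors, prior elicitation from legacy survey summaries or
    expert quantile intervals, Monte Carlo audits of returned sample
    sizes, and a runner that turns a table of per-district legacy
    summaries into complete sample-size tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
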
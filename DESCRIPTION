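Package: cfufit
Title: Censored Lognormal Fitting for Microbial Enumeration Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood estimation of the mean and standard deviation
    of a log10-normal microbial concentration distribution from plate-count
    enumeration data that contain left-censored results (below the limit of
    quantification, "not detected") and interval-censored (semi-quantitative)
    results.  Provides the censored-data log-likelihood, a robust
    two-parameter optimiser with Wald confidence intervals and distribution
    percentiles, parsers for the common quantitative and interval CSV
    layouts, a limit-of-quantification calculator for standard plating
    schemes, a simulator for parameter-recovery and substitution-bias
    studies, and report/plot-table generation.  Fitted concentration
    distributions are the standard exposure inputs of quantitative microbial
    risk assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    fitdistrplus
Config/testthat/edition: 3
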
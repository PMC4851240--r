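Package: blindsr
Title: Type I Error Inflation from Worst-Case Blinded Sample Size Reassessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the maximum type I error rate attainable by an
    adversarial (worst-case) second-stage sample size reassessment after a
    blinded interim analysis of a two-arm superiority trial, when a secondary
    endpoint with a treatment effect partially unblinds the data. Implements
    the bivariate-normal two-endpoint model, Bayes posterior treatment
    allocation probabilities, the normal approximation to the conditional law
    of the first-stage z-statistic, the closed-form worst-case second-stage
    sample size rule with and without bounds, exact enumeration and MCMC over
    balanced allocations, block-randomization machinery, and vectorised Monte
    Carlo drivers for the resulting maximum type I error rate and for the
    unblinding correlation between blinded and unblinded effect estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
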
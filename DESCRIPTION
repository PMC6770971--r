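Package: bfmeth
Title: Bayes Factor Detection of Differentially Methylated Regions for
    Ordinal Disease Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects differentially methylated regions (DMRs) whose
    methylation rates increase monotonically with ordinal disease severity
    from bisulfite-sequencing count data. Within each moving window of CpG
    sites a mixed-effect Bayesian logistic model is fitted to binomial
    methylation counts by Polya-Gamma Gibbs sampling; posterior and prior
    draws of the group effects are passed through a covariance-weighted
    min-max isotonic transformation and combined into an order-restricted
    Bayes factor with Jeffreys evidence categories. Includes a
    branching-process short-read simulator that reproduces the spatial
    correlation of methylation states along a CpG island, plus a
    simulation-study layer for calibrating empirical Bayes-factor cutoffs
    and power by number of differentially methylated CpG sites per window.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
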
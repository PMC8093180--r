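Package: pgsnurture
Title: Genetic Nurture and Vertical Transmission from Transmitted and
    Nontransmitted Polygenic Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural equation models for estimating vertical transmission,
    genetic nurture, and additive genetic variance from the transmitted and
    nontransmitted haplotypic polygenic scores of parent-offspring trios.
    Provides analytic equilibrium expectations under primary phenotypic
    assortative mating (copath models), full-information maximum likelihood
    fitting with nonlinear equilibrium constraints, moment-based tests of
    assortative-mating mechanisms, construction of haplotypic scores from
    phased or unphased trio genotypes, and a forward-time variant-level
    family simulator used to validate the analytic expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
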
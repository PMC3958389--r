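Package: cnimap
Title: Mapping Cyto-Nuclear Interaction QTL Subject to Genomic Imprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interval mapping of quantitative trait loci (QTL) whose effects
    involve cytoplasmic (maternal) effects, genomic imprinting, and
    cyto-nuclear interactions in reciprocal backcross and reciprocal F2
    designs derived from inbred lines. Implements the eight-parameter
    genetic model (overall mean, cytoplasmic, additive, dominance,
    imprinting effects and the three cytoplasm-by-nuclear interactions), a
    four-component Gaussian mixture likelihood with design-constrained
    means maximised by EM, QTL genotype posteriors from flanking markers
    using sex-specific recombination fractions, genome scans with
    permutation thresholds, a battery of likelihood-ratio tests at
    detected QTL, and a seeded Monte Carlo simulator of reciprocal
    crosses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    optparse,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
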
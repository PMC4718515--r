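Package: pedvc
Title: Variance-Component Analysis of Extended-Pedigree Family Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for family-based genetic epidemiology on extended
    pedigrees: recursive kinship and household covariance construction,
    maximum-likelihood variance-component estimation of heritability and
    shared-household effects for continuous traits, liability-threshold
    (probit) models for binary disease traits with proband-ascertainment
    correction, bivariate models for genetic and environmental
    correlations between traits, and measured-genotype association
    testing with quality-control filters and genomic-inflation
    diagnostics. A synthetic family-study generator (pedigrees,
    polygenic traits with household effects and covariates,
    threshold-liability disease status, gene-dropped genotypes) makes
    every stage of the pipeline testable without access to study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    numDeriv,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    mvtnorm,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
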
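Package: mppme
Title: Multi-Parent Multi-Environment QTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint QTL analysis of multi-parent populations (MPPs) tested in
    multiple environments. Implements three QTL allele codings (parental,
    ancestral, bi-allelic) built from identity-by-descent probabilities of
    doubled-haploid progeny, and four detection strategies: scans on genotype
    BLUEs averaged across environments, per-environment scans, a two-stage
    joint multi-environment model, and a one-stage model on plot data. The
    multi-environment models use a compound-symmetry genotypic covariance
    with environment-cross-specific error variances, fitted by restricted
    maximum likelihood, with Wald tests on allelic substitution effects.
    Environment-specific QTL effects can be decomposed into a main effect and
    a sensitivity to an environmental covariate such as precipitation. A
    nested-association-mapping simulator with known truth supports validation
    end to end.
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
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
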
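Package: supramult
Title: Supra-Multiplicativity Testing for SNP Sets in Case-Control Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-degree-of-freedom logistic-regression test for
    supra-multiplicativity of risk-allele effects in pre-specified SNP sets
    of size 2 to 500, with a Bonferroni-corrected scan over risk-allele-load
    thresholds.  Includes the standard single-marker, dominance and two-/
    three-way interaction tests used as comparators, simulators for
    multiplicative null models, limiting-pathway liability models (plain and
    SNP-weighted), three-SNP recessive models and LD-tagged proxy markers,
    and a study runner that estimates empirical type-I error and power over
    replicate simulations.  Genotypes are read from minimal VCF or dosage
    tables and oriented to externally designated risk alleles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
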
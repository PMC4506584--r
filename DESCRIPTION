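Package: epijack
Title: Case-Only Gene-Gene Interaction Tests for Imputed SNPs with
    Jackknife Variance Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Wald-type tests for gene-gene (SNP-SNP) interaction in
    case-only studies when one or both markers are untyped and only
    marginally imputed genotype posterior probabilities are available.
    Interaction is parameterised by the four local log odds ratios of the
    3x3 joint genotype table; the null of multiplicative penetrances is
    beta = 0.  Provides the unconstrained Wald-type test (chi-square with
    4 df) and a sign-constrained variant referred to a chi-bar-square
    mixture, with a delete-1 jackknife variance estimator that propagates
    imputation uncertainty, the naive plug-in dosage variance for
    comparison, an emulator of marginal single-tag imputation for
    simulation studies, and a reproducible size/power study harness.
    Includes readers and writers for Oxford GEN-style genotype
    probability files and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
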
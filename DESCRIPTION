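Package: micropls
Title: Compositional PLS-DA and Bayesian Differential Abundance for
    Microbiome Count Tables
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of 16S amplicon count tables for two-group
    comparisons: alpha and beta diversity with permutation tests (PERMANOVA,
    PERMDISP), additive log-ratio (ALR) transformation with lowest-CV
    reference selection and Procrustes verification, partial least squares
    discriminant analysis (PLS-DA) with Mahalanobis centroid classification,
    balanced-error-rate cross-validation, iterative VIP variable selection
    and permutation testing, and Bayesian two-group differential abundance
    via Gibbs sampling with posterior error probability (PEP) based false
    discovery control. Includes a logistic-normal multinomial synthetic
    data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
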
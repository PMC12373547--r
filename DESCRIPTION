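Package: epiGP
Title: Multi-Kernel Genomic Prediction with Partitioned Epistasis for
    Multi-Program Wheat Breeding Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide prediction in inbred wheat breeding
    populations assembled from several breeding programs. Implements an
    unweighted two-stage phenotypic analysis (within-environment BLUEs with
    Bonferroni-Holm/MAD outlier correction, across-environment BLUPs and
    reliability), merging and quality control of heterogeneous SNP panels
    (structural filters, minor-allele-frequency and missingness thresholds,
    imputation, Rogers' distance, principal coordinate analysis, LD-based
    effective population size), additive and additive-by-additive epistasis
    kernels (VanRaden relationship matrix and its Hadamard square, restricted
    to subgenomes or chromosomes), Bayesian multi-kernel GBLUP fitted by Gibbs
    sampling with a closed-form BLUP oracle, and orchestration of
    training-set-combination and training-size validation scenarios. A
    synthetic-data generator emulates multiple partially connected breeding
    series with heterogeneous marker panels and a deeply replicated
    high-heritability test set, so the full pipeline can be exercised and
    tested without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
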
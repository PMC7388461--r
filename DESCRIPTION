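Package: hologen
Title: Hologenomic Prediction of Quantitative Traits with Genomic,
    Microbial and Genome-by-Microbiome Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-kernel Bayesian mixed models for predicting
    quantitative traits from host genotypes and gut microbiome
    composition. Builds a VanRaden genomic relationship matrix, a
    microbial relationship matrix from log-standardized OTU relative
    abundances, and their Hadamard product for genome-by-microbiome
    interaction; fits the resulting reproducing kernel Hilbert space
    (RKHS) regression models by Gibbs sampling with eigendecomposition
    updates; estimates heritability, microbiability and interaction
    variance fractions; performs single-feature preselection scans with
    Bonferroni selection, sire-stratified cross-validation with masked
    phenotype prediction, and a factorial post-analysis of predictive
    abilities with type-III ANOVA and least-squares means. Includes a
    simulator for half-sib populations with genotypes, stage-wise OTU
    tables and phenotypes of known variance partition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
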
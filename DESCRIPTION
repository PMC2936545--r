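Package: llnet
Title: Integrative Expression-Genotype-Lipid Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for integrative analysis of blood
    transcriptomics, genome-wide genotypes and serum lipid traits:
    technical-replicate quality control and quantile normalization,
    gender-stratified trait standardization with Box-Cox, univariate and
    multivariate (Wilks' lambda) trait-expression association with
    Bonferroni control, weighted co-expression network construction with
    soft thresholding, dynamic tree cut and module eigengenes,
    permutation-calibrated cis/trans eQTL scans, and structural-equation
    edge orienting with genetic anchors (LEO scores). Ships a synthetic
    data generator with planted modules, eQTLs and causal topologies for
    end-to-end validation.
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
    nortest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    MASS,
    optparse,
    limma,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
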
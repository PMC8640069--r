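Package: epicohort
Title: Integrative Epigenome, Transcriptome and Genotype Analysis of
    Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrative molecular epidemiology of case-control
    cohorts profiled for whole-blood DNA methylation, RNA-seq gene
    expression, genome-wide genotypes and classical HLA allele dosages.
    Implements covariate-adjusted scans for differentially methylated
    positions and differentially variable positions (Brown-Forsythe test on
    covariate residuals), GSEA-style detection of differentially methylated
    regions with permutation significance and leading-edge extraction,
    region-methylation versus gene-expression correlation (eQTM), a
    simplified negative-binomial Wald test for differential expression,
    cis-meQTL/eQTL mapping, genotype-by-disease interaction QTL discovery
    with a replication-aware disease-dependent filter, mediation-direction
    classification, an HLA stratified/conditional association suite, and a
    synthetic multi-omics cohort simulator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    matrixStats,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
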
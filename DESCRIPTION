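Package: loadrisk
Title: Polygenic and Phenotypic Risk Prediction of Late-Onset Alzheimer's
    Disease with k-Nearest Neighbours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for case/control risk prediction of late-onset
    Alzheimer's disease (LOAD) from genotype and clinical data: genotype
    quality control (zero-variance, missingness and minor-allele-frequency
    filters for SNPs and individuals), a control-standardized weighted
    polygenic score, APOE epsilon-haplotype diplotype calling from rs429358
    and rs7412 with ordinal risk encoding, phenotype encoding, a from-scratch
    k-nearest-neighbours classifier with Euclidean, Manhattan and cosine
    distances, class rebalancing by over- or subsampling, cross-validated
    selection of k, decision-threshold tuning for sensitivity, full
    confusion-matrix/ROC evaluation, and the case-versus-control inferential
    battery (Welch tests, Hedges' g, chi-square independence, Cramer's V).
    A liability-threshold synthetic cohort generator emulates the statistical
    structure of a biobank-style case/control cohort so every stage is
    testable without access to individual-level data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
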
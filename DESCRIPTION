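Package: famvar
Title: Familial Rare-Variant Discovery from Multi-Family Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for candidate-gene discovery in
    families with multiple affected members sequenced by whole-exome
    sequencing. Implements per-family shared-variant extraction with a
    cascading quality/rarity filter, cross-family exclusion of partially
    shared variants, one-sided Fisher enrichment against a
    population-specific control cohort, ensemble deleteriousness
    classification (CADD plus six-predictor voting with a dominant-model
    allele-count ceiling), cross-family gene burden and recurrent-variant
    analysis, copy-number screening, hypergeometric gene-set enrichment
    with Benjamini-Hochberg correction, and cohort quality control
    (Ti/Tv, heterozygosity ratio, read-level VAF screening, KING-robust
    kinship, PCA stratification). A fully synthetic cohort generator with
    planted ground truth makes every stage testable without access to
    restricted patient data.
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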
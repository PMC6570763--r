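Package: vloh
Title: Variegated Loss of Heterozygosity from Allele-Specific Expression in F1 Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies allele-specific expression at strain-informative
    expressed SNVs (eSNVs) in F1 hybrid tumor cohorts and detects variegated
    loss of heterozygosity (V-LOH). Converts strain allele counts to BALB/c
    allele frequencies (CAF), calls per-tumor clonality from X-inactivation
    skew, detects cohort-wide concerted LOH and builds the exclusion mask,
    flags per-tumor allelic-ratio outliers by cohort Z-score, tests gene-level
    outlier enrichment against a Poisson null with an exact binomial test, and
    correlates per-tumor outlier burden with gene expression. A synthetic-data
    generator produces F1 allele-count and expression tables with planted
    clonal and stochastic events so every stage is verifiable end to end.
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
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
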
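Package: ctdnadyn
Title: Paired ctDNA Alteration Dynamics, Mutational Signatures and
    Biomarker Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for longitudinal circulating tumor DNA (ctDNA)
    studies with paired baseline and end-of-treatment samples. Classifies
    somatic alterations as acquired, maintained or lost between timepoints,
    aggregates them to gene level with a fixed precedence rule, quantifies
    clonality as the ratio of variant allele frequency to the sample maximum
    (maxVAF), models per-patient mutation-acquisition rates with a Poisson
    mixture (EM with time-on-treatment offsets) and compares arms by
    negative-binomial regression, builds 96-channel single-base-substitution
    spectra and refits exposures against a reference signature matrix by
    non-negative least squares, scores bulk expression profiles (cytolytic,
    immune and weighted z-score subtype scores, single-sample GSEA), ranks
    genes by Cox-model association with survival for preranked gene set
    enrichment analysis, and fits Kaplan-Meier and Cox models including
    treatment-by-biomarker interaction tests. A synthetic-cohort generator
    with known generative truth makes every stage testable without access to
    restricted patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
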
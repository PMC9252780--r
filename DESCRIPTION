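Package: pcphewas
Title: Gene-Based Phenome-Wide Association Scans Using Genotype Principal Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-level association scans of common genetic variants using
    per-gene principal components of genotype dosages. Implements nested-model
    association tests (F-test for continuous outcomes, analysis of deviance for
    binary outcomes), multiplicity control (Storey q-values, Bonferroni, the
    genomic inflation factor lambda and quantile-quantile plot coordinates),
    cis-Mendelian randomization using gene principal components as instruments
    combined with the inverse-variance-weighted estimator, and drug-target
    enrichment over the hierarchical ATC drug classification. A synthetic-data
    module generates LD-structured dosages, phenotypes with covariate
    confounding, kinship pairs and Mendelian-randomization scenarios with known
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
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
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
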
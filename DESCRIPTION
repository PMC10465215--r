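Package: hdscore
Title: Histone Deacetylase Program Scoring of the Tumor Microenvironment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates a transcriptome-derived histone deacetylase
    (HDAC) score for gastric cancer cohorts. From a gene-by-sample expression
    matrix and a survival table, the package discovers regulator-driven
    molecular subtypes by consensus non-negative matrix factorization, screens
    subtype-associated genes for prognostic value with moderated F tests and
    univariate Cox regression, reduces the prognostic gene list with Boruta
    shadow-feature selection, and summarizes the surviving protective and risk
    gene programs into a per-sample score as the difference of two first
    principal components. Downstream evaluation covers Kaplan-Meier and
    log-rank survival contrasts, single-sample gene-set enrichment (ssGSEA)
    correlation with immune signatures, and immunotherapy response prediction
    combining the score with PD-L1 combined positive score and microsatellite
    instability status. A synthetic-cohort generator with planted subtypes,
    proportional-hazards gene programs, immune-signature structure and a
    logistic response model provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    limma,
    mclust,
    withr
Config/testthat/edition: 3
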
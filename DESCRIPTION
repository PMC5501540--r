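Package: modburden
Title: Rare-Variant Modifier-Gene Burden Analysis for Extreme-Phenotype Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modifier-gene discovery in small extreme-phenotype
    sequencing designs: rare-variant quality filters (missingness, impact
    class, reference-population MAF, exact binomial allelic balance),
    gene-class burden aggregation and Fisher exact comparisons between
    phenotypic extremes and against a reference cohort, covariate-adjusted
    SKAT-style variance-component score tests with per-SNP partial scores
    and leave-one-out influence analysis, pathogenicity-predictor ROC
    benchmarking with the paired DeLong test, and a Poisson mutational-load
    power model with misclassification adjustment. A synthetic-data module
    generates cohorts, genotype matrices, read depths and predictor scores
    with the statistical structure the analysis assumes, so the whole
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
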
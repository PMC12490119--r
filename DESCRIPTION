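Package: pretermASD
Title: Genetic Liability and Prematurity Analyses for Autism Spectrum Disorder Cohorts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studying how rare de novo and inherited
    variant burden, polygenic risk, preterm birth, and phenotype
    multimorbidity jointly relate to autism spectrum disorder (ASD) in
    family-based cohorts. Implements a trio de novo variant quality-control
    cascade with per-filter auditing, inheritance-mode classification of rare
    variants in neurodevelopmental-disorder gene panels (including a
    compound-heterozygote scan), allelic polygenic scoring with cohort
    standardization, prevalence/odds-ratio/multimorbidity statistics,
    family-clustered generalized estimating equation (GEE) models with
    sandwich variances, and a nested cross-validation prediction procedure
    with recursive feature elimination and SHAP attributions. A synthetic
    multi-child-family cohort generator with plantable variant artifacts
    makes every stage testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    randomForest,
    xgboost,
    e1071,
    pROC,
    caret
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
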
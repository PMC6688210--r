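Package: methylancestry
Title: Ancestry Inference from Placental DNA Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers ethnicity/ancestry composition from Illumina methylation
    array beta values. Provides the full analysis chain: a quality-control and
    filtering cascade for beta matrices (platform overlap, detection/bead-count
    failures, KNN imputation, cross-hybridizing and non-variable probe removal,
    sex concordance checks, inter-array correlation, beta-mixture quantile
    normalization), a penalized multinomial classifier with
    probability-threshold "Ambiguous" calls, a leave-one-dataset-out evaluation
    harness, a PCA variance-explained framework for comparing
    population-structure methods, Fisher-exact enrichment characterization of
    predictive sites, and a seeded generator of population-structured synthetic
    methylation cohorts with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    nnet,
    optparse,
    withr
Config/testthat/edition: 3
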
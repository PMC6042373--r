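Package: pafar
Title: Prioritization and Functional Assessment of Noncoding Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Supervised prioritization and functional annotation of noncoding
    variants associated with complex diseases. Implements population
    differentiation metrics (an unbiased F_ST estimator and a dispersion
    score computed from subpopulation allele frequencies), assembly of sparse
    variant-by-feature matrices from annotation tracks, conservation scores
    and population metrics, curated construction of labeled training sets,
    an L1-regularized sparse logistic regression scoring model, gene-centric
    weighted annotation scores, and variant set enrichment analysis via
    Fisher's exact test. Ships seeded synthetic-data generators so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    glmnet,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
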
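Package: seq2expr
Title: Individual-Level Protein Expression Prediction from Personal Genome
    Sequence at Desk Scale
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, desk-scale pipeline for predicting individual-level
    protein expression (NPX-like phenotypes) from personalized genome
    sequence. Implements dosage-weighted one-hot encoding of personal
    genomes from VCF plus reference FASTA (0/0.5/1 convention), an
    elastic-net cis-heritability baseline on the dosage matrix, a small
    trainable convolutional sequence-to-expression surrogate with a
    pooled-embedding + covariate MLP head and a composite
    MSE/pairwise-difference loss, in-silico mutagenesis scoring with
    high-scoring-variant selection matched to the elastic-net support,
    rare-variant masking, chromatin-state enrichment, cCRE overlap, PWM
    log-odds motif-effect classification with exact p-values, and LD
    redundancy statistics. A synthetic cohort generator with planted
    genetic architecture makes every stage testable without restricted
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    glmnet,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
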
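Package: stressGRN
Title: Regulatory Network Inference from Time-Course Stress Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of a regulatory
    network analysis pipeline for time-course abiotic-stress RNA-seq:
    TMM normalization and CPM filtering of raw counts, per-time-point
    negative-binomial exact-test differential expression, Pearson
    co-expression network construction between transcription factors and
    target genes, Network Component Analysis (NCA) decomposition of
    expression into connectivity and transcription-factor activities under
    rank identifiability constraints, validation of predicted interactions
    by ortholog transfer and by Wang GO semantic similarity with a
    randomized background test, a tree-structured Gaussian-emission
    temporal model with bifurcation events and hypergeometric TF split
    scores, and GO term enrichment (classic and elim). A synthetic-data
    generator plants a ground-truth network, activities, bifurcations and
    ortholog/GO structure so that every stage of the pipeline is
    verifiable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
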
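Package: termOmics
Title: Term-Seq 3' End Calling and Thermal-Stress Multi-Omics Analysis for
    Archaea
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing transcription termination and thermal-stress
    responses in hyperthermophilic archaea. Implements consensus calling and
    classification of Term-seq 3' ends from strand-specific end-count tracks,
    poly(U) terminator and BRE/TATA promoter sequence-feature analysis with
    exact position-weight-matrix p-values, position-specific nucleotide
    enrichment against intergenic background, simplified negative-binomial and
    moderated-t differential tests with a five-level regulation grouping,
    length-bias-aware functional category enrichment using the Wallenius
    noncentral hypergeometric distribution, and integrative clustering of RNA
    and protein fold-change profiles. A synthetic-data generator with planted
    ground truth (3' ends, promoters, terminators, differential expression,
    profile clusters, enriched categories) makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    DESeq2,
    mclust,
    withr
biocViews: Transcriptomics, Proteomics, GeneExpression, Sequencing,
    DifferentialExpression, Clustering
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
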
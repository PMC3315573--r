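Package: tagProteo
Title: Dual Tag-Seq and Spectral-Count Proteomics Differential Abundance
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for paired digital gene expression
    (NlaIII-anchored 21-bp tag-seq) and label-free spectral-count proteomics
    of a two-condition, replicate-free experiment. Provides in-silico NlaIII
    tag extraction, exact-match genome tag mapping with uniqueness filtering
    and strand-aware gene assignment (with configurable 3'-UTR extension),
    tags-per-million normalization, an empirical-Bayes differential
    expression model for two pooled libraries (posterior mean log2 ratio,
    shrunken standard error, local false discovery rate), Fisher exact
    differential protein abundance on normalized spectral counts, and
    transcript-protein fold-change integration with concordance regression.
    A synthetic-data generator emulating the tag-seq protocol (incomplete
    digestion, antisense tags, sequencing error) and a correlated proteome
    makes every stage testable without external deposits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, Proteomics, DifferentialExpression, Bayesian,
    Sequencing, Software
RoxygenNote: 7.3.3
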
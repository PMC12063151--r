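Package: lncscout
Title: Identification, Triplex Interaction and Co-Expression Analysis of
    Long Non-Coding RNAs
Version: 1.0.0
Authors@R:
    person("lncscout", "developers", email = "lncscout@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for annotating long non-coding RNAs
    (lncRNAs) from genome-guided transcriptome assemblies of compact
    (yeast-like) genomes and for generating functional hypotheses about them.
    Implements the canonical filtering cascade (length, sense-exon overlap,
    coding potential, known-RNA and protein-domain hits, expression),
    positional classification of lncRNAs relative to their nearest
    protein-coding gene, RNA-DNA triplex TFO/TTS motif search with a
    priority-based genomic-context scheme, gene-level expression aggregation,
    normalisation and lncRNA-gene correlation analysis stratified by
    differential expression, and fuzzy c-means soft clustering of expression
    profiles. A seeded synthetic-data generator with recorded ground truth
    makes every stage verifiable without external downloads.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
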
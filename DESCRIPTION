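Package: epimark
Title: Integrative Analysis of Repressive Histone-Mark ChIP-Seq and Digital Gene Expression
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide integration of a repressive histone mark
    (H3K27me3-style) ChIP-seq with tag-based digital gene expression (DGE)
    profiling. Partitions a genome into promoter-flank, exon, intron,
    downstream-flank and intergenic classes and summarises read distribution
    and abundance per class; builds TSS-anchored, metagene and promoter-window
    tag-density profiles; associates enrichment peaks with genes by a 1 bp
    overlap rule; extracts CATG-anchored 21 bp DGE tags, maps them with at most
    one mismatch, normalises to tags per million and tests two-library
    differential expression with an exact count test; compares promoter-window
    modification densities between sample groups; computes ChIP-qPCR
    standard-curve efficiencies and 2^-ddCp fold enrichments; and ships a
    seeded synthetic-data generator that plants the expression-coupled promoter
    enrichment geometry the analysis is designed to recover.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    Matrix,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
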
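Package: altisplice
Title: Junction-Based Cassette-Exon PSI and Cross-Species Transcriptome
    Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A self-contained comparative-transcriptomics pipeline for
    multi-species, multi-tissue RNA-seq designs. Quantifies cassette-exon
    inclusion (percent spliced in, PSI) from splice-junction reads using
    junction libraries built with a k-8 exon retrieval rule and a
    k-mer-mappability normalization, applies read quality-control filters,
    computes a simplified exon-union FPKM expression measure, and compares
    samples across species with correlation summaries, bootstrapped
    neighbor-joining expression trees, average-linkage hierarchical
    clustering, principal component analysis, and principal variance
    component analysis (PVCA). Includes a deterministic multi-species
    RNA-seq simulator (genomes, annotations, orthology, truth tables,
    FASTQ reads) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
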
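Package: teeco
Title: Transposable Element Ecosystems in Developmental Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs transposable element (TE) loci from fragmented
    repeat annotations, estimates family ages from Kimura two-parameter
    divergence and neighbor-joining terminal branch lengths, characterizes
    the genomic distribution of TE classes relative to genes, classifies
    the transcriptional provenance of each locus (gene-dependent versus
    self-expressed), and clusters developmental expression profiles with
    class and superfamily enrichment tests. Ships a synthetic-genome
    simulator that plants insertions with known ages, fragmentation and
    expression provenance so that every stage of the pipeline can be
    validated against ground truth.
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
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
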
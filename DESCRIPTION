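Package: nanosplice
Title: Targeted Long-Read Amplicon Splice-Variant Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and characterisation of alternative-splicing transcript
    variants of a single gene from targeted nanopore amplicon sequencing.
    Extracts and quantifies splice junctions from spliced long-read alignments,
    snaps noisy junction coordinates to annotated splice sites, discovers
    cryptic exons, collapses full-length reads into an exon-chain isoform
    catalogue, predicts open reading frames with annotated or alternative
    initiation codons, flags premature termination codons and candidates for
    nonsense-mediated decay, and maps protein-domain presence across isoforms.
    Ships a fully synthetic ELF3-like gene fixture and a seeded nanopore-style
    read simulator so the whole pipeline is runnable and testable without any
    external data or aligner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicAlignments,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    methods,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
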
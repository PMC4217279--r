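Package: tracktools
Title: Read Mapping Classification and Prokaryotic RNA-Seq Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies read mappings from SAM/BAM files into Perfect, Best
    and Common Match quality classes with Single Best Match flagging, and
    runs downstream analyses on the classified tracks: read-pair concordance
    classification, SNP/DIP detection with codon-level effect annotation,
    transcription start site and novel transcript detection with automatic
    parameter estimation, operon detection from spanning reads, RPKM and
    read-count quantification, feature and general coverage analyses, and
    the Express test for rapid two-condition differential expression
    screening. Reference genomes are read from FASTA, GenBank, EMBL, GFF2
    and GFF3. Includes a seeded simulator producing references and aligned
    reads with planted variants, TSSs, operons and expression differences
    for fully self-contained validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    igraph,
    optparse,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
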
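Package: clipmap
Title: Binding-Site Definition, Motif Analytics and RNA Splicing Maps for iCLIP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis of iCLIP data for a splicing-regulatory
    RNA-binding protein: read-level preprocessing rules (barcode quality
    filtering, demultiplexing, adapter trimming, random-barcode
    deduplication), definition of reproducible 9-nt binding sites from scored
    single-nucleotide crosslink sites, transcript-region assignment under
    GENCODE-style annotation filters, pentamer and GAA/UUC triplet motif
    analytics, cassette-exon filtering of rMATS tables, and position-dependent
    RNA splicing maps with PSI-matched resampled backgrounds. A synthetic-data
    generator with planted motifs and regulated exons makes the whole pipeline
    runnable and testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
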
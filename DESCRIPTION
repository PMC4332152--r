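Package: nucleomux
Title: Multiplexed Barcoded ChIP-Seq Analysis of Nucleosomal Chromatin
Version: 0.1.0
Authors@R:
    person("Nucleomux", "Developers", email = "maintainer@nucleomux.org",
           role = c("aut", "cre"))
Description: Tools for analysing multiplexed, barcoded chromatin
    immuno-precipitation sequencing of MNase-derived mono-nucleosomes.
    Covers inline-barcode demultiplexing of paired-end reads,
    mono-nucleosomal fragment filtering and PCR-duplicate capping,
    nucleosome-midpoint occupancy tracks and TSS meta-profiles,
    input-normalised per-position negative-binomial differential testing
    of histone-mark occupancy with local false discovery rates, and
    detection of genes gaining internal (cryptic) transcription
    initiation from 5' end tag data. A synthetic multiplexed-chromatin
    generator with full ground truth makes every stage testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    withr,
    jsonlite,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
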
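Package: plastedit
Title: Detection and Comparative Analysis of Plastid RNA Editing from
    Aligned RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Pileup-based detection of C-to-U and U-to-C RNA editing sites
    in organellar (plastid) transcriptomes from aligned RNA-seq reads.
    Provides alignment filtering by length fraction and similarity,
    strand-aware per-position base counting, editing-site calling with
    coverage/count/frequency thresholds and homopolymer masking,
    editing-efficiency classification, feature and codon-consequence
    annotation (start/stop-codon creation, synonymy, hydropathy change),
    nearest-neighbour sequence-context profiling, differential-editing
    analysis between tissues, RPKM expression quantification, and a
    deterministic synthetic-plastome read simulator with planted edits for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    jsonlite,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
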
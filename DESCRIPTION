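Package: medipstrand
Title: Strand-Specific DNA Methylation Calling from MeDIP-Seq Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes MeDIP-Seq DNA-methylation peaks into strand-specific
    signals (plus-stranded, minus-stranded or double-stranded) using an
    integer-rate Poisson likelihood-set decision rule on first-mate read
    counts. Includes filtered first-mate extraction from paired-end
    alignments, per-cycle base-frequency QC of strand-preserving libraries,
    strand-aware interval overlap counting, derivation of gene-anatomy and
    splice-junction features from GFF3 annotation, splice-site sense/antisense
    asymmetry testing, gamma-Poisson feature-normalised methylation
    distributions with simulated credible intervals, BS-Seq concordance
    tallies, and a seeded synthetic-data generator emulating strand-preserving
    MeDIP libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    GenomicAlignments,
    Rsamtools,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    methods,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
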
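Package: TUscape
Title: Mapping the Transcriptional Landscape of a Bacterial Genome from
    Tiling Arrays and RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the vegetative transcriptional landscape of a
    high-GC bacterial chromosome from two strand-specific expression
    platforms: a two-channel (mRNA versus genomic-DNA baseline) tiling
    microarray and per-base RNA-Seq coverage.  Significantly hybridizing
    probes are merged into transcribed segments, combined with coverage
    step boundaries and a gene annotation into transcriptional units
    (TSS, TTS, untranslated regions, fold-change class), and each unit is
    then annotated with a sigma-70-style -35/-10 promoter learned by a
    constrained two-box EM, a rho-independent terminator found by a
    hairpin/polyT detector, and a termination-strategy class.  A random
    forest ranks which promoter features discriminate transcription
    level, and transcribed intergenic segments are reported as candidate
    housekeeping sRNAs.  A seeded synthetic-genome generator with planted
    ground truth emulates the statistical structure of the study system
    for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: Transcriptomics, GeneRegulation, Sequencing, Microarray,
    MotifDiscovery, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
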
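Package: ssingleP1
Title: Genome-Wide Profiling of Endogenous Single-Stranded DNA from 3'-OH Terminus Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for SSiNGLe-P1 style sequencing experiments that
    map endogenous single-stranded DNA (essDNA) through limited P1 endonuclease
    digestion and 3'-OH terminus capture. Provides structural filtering and tag
    trimming of polyG/polyT anchored paired-end reads, extraction of 3'-OH
    terminus coordinates from read-2 alignments with an A-rich internal-priming
    filter, mitochondrial strand-displacement analytics (H/L strand ratios in
    three counting modes, essDNA indices over the Q1-Q4 partition), a
    SICER-parameterized Poisson window island caller for essDNA regions against
    an untreated control, shuffle-based null simulation, odds-ratio enrichment
    against genomic element sets, promoter/TSS proximity and expression
    analyses, and a synthetic-data generator that makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    graphics,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
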
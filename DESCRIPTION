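Package: cgescan
Title: Whole-Genome Transcript Expression Profiling with the CGE Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed coverage-threshold region detection over a
    chromosome-level genome, the chromosome genome expression (CGE)
    percent index comparing two or more conditions per locus,
    mRNA-miRNA opposition calls, flank sequence extraction, Circos-ready
    track export, and companion feature-level statistics (Pearson TPM
    correlation screen, Manhattan-distance k-medians clustering,
    delta-delta-Ct relative quantification). Includes a coverage and
    expression simulator with planted ground truth for end-to-end
    validation of every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
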
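Package: promstate
Title: Promoter Chromatin State Analysis for Tiled ChIP Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for promoter tiling-array ChIP data
    (ChIP-chip) profiling histone modifications (H3K4me3, AcH3, H3K27me3)
    across hematopoietic differentiation. Implements background and
    histone-H3 normalization of probe intensities, sliding-window
    permutation peak calling with empirical FDR control, peak-to-promoter
    assignment, TSS-anchored metaprofiles, 8-way combinatorial chromatin
    state classification, state-transition dynamics between cell types,
    rank-invariant expression normalization with fold-change/P differential
    calls, and mark-vs-expression enrichment statistics. A synthetic-data
    generator with planted ground truth emulates the tiling-array and
    expression-array design so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    withr,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
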
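Package: prcmeth
Title: PRC2, H3K27me3 and DNA Methylation Crosstalk During ESC Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of the relationship between Polycomb
    Repressive Complex 2 (PRC2) activity, its H3K27me3 mark, DNA methylation
    and gene expression during directed differentiation of embryonic stem
    cells to spinal motor neurons. Provides RRBS-style per-CpG methylation
    summarization with coverage filtering, a two-dimensional binned
    methylation-comparison statistic with a replicate-based null model,
    ChIP-seq TSS-window and metagene quantification, bivalent-promoter
    resolution classification, a proximity cascade assigning CpGs to genes,
    quintile and segmented-regression expression integration, and a
    synthetic multi-omics cohort generator with planted effect sizes so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
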
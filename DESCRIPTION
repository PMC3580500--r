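Package: cpgchrom
Title: Comparative Chromatin Profiling of CpG-Island and Non-CpG Promoter Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis workflow for comparing the chromatin organization of
    genes with CpG-island promoters against genes with CpG-poor promoters.
    Provides promoter classification (CpG-island overlap and the windowed
    CpG observed/expected + GC-content scan into high/intermediate/low CpG
    promoter classes), expression-tiered and expression-matched gene-set
    construction, conversion of mapped sequencing reads into deduplicated,
    dyad-shifted, depth-rescaled per-base count tracks, TSS-anchored
    strand-oriented profile matrices with loess smoothing and
    nucleosome-background subtraction, GC-content and interval-density
    metagene profiles, and the study-specific statistics: promoter asymmetry
    scores, expression-coupled modification peak-shift correlation, and
    CTCF-overlap enrichment across expression bins. A synthetic-data module
    generates gene models, promoter sequences, expression values, and
    chromatin reads with the statistical structure the analysis assumes, so
    the entire pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
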
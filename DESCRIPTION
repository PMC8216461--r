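Package: methsplice
Title: Sensing Intragenic DNA Methylation Through Alternative Splicing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cassette-exon inclusion from splice-junction
    read counts with an anchor-exon percentage statistic, calling differentially
    methylated regions (DMRs) from binned MeDIP/MIRA-style enrichment counts with
    TMM scale factors and Bonferroni correction, and classifying shared
    differential-splicing events by the direction concordance between splicing
    change and local methylation change across two cellular systems. Includes
    qPCR-style relative quantification (reference-gene normalization and the
    splicing index), sample QC filtering, paired differential-expression calls,
    and a coupled methylation-splicing simulator built around a CD44-like
    multi-exon gene model, so the full pipeline can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    edgeR,
    limma,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
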
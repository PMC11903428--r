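Package: ChIPpanel
Title: Replicate-Validated Histone ChIP-seq Peak Sets, Tissue Panels and
    Signal Tracks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream processing of histone-modification ChIP-seq peak
    calls: fold-enrichment filtering and reciprocal replicate validation
    into combined peak sets, FRiP and genome-coverage quality metrics,
    peak-width and caller-overlap summaries, tissue-unique peak
    identification across a multi-tissue panel with read-depth correlation
    diagnostics, TSS-anchored genomic feature annotation, and signal
    extraction scaling (SES) of input-subtracted, replicate-averaged
    coverage tracks. Includes a deterministic synthetic-data generator
    with planted ground truth so the whole pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
biocViews: ChIPSeq, Epigenetics, FunctionalGenomics, PeakDetection,
    QualityControl, Coverage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
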
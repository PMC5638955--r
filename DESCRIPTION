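Package: ptascreen
Title: Colony Growth-Rate Screening and Promoter Conserved-Region Analysis
    for Programmable Transcriptional Activator Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the two computational stages of a synthetic
    incompatibility screen. Stage one estimates colony growth rates from
    flatbed-scanner time-lapses of petri dishes: HSV value-channel
    extraction, first-frame background subtraction, Gaussian smoothing,
    global thresholding, seed detection on a temporal z-projection, seeded
    splitting of merged colonies on the distance transform, per-colony area
    tracking with edge and ambiguous-merge exclusions, and a 12-hour
    moving-window maximum log-linear slope estimator, with one-way ANOVA and
    Tukey post-tests for group comparisons, plus a semilog slope estimator
    for plate-reader OD curves. Stage two scans 1-kb strand-aware promoter
    windows for SNP-free conserved regions, summarises targetable regions
    (longer than 30 bp) and their positions relative to gene starts, and
    enumerates candidate NGG-PAM protospacer sites within conserved regions.
    A synthetic-data module generates plate time-lapses, OD curves and
    genome/variant sets with known ground truth so every stage is testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    vcfR,
    tiff,
    yaml,
    optparse,
    jsonlite,
    methods,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
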
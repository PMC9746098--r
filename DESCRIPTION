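Package: svconsensus
Title: Multi-Platform Somatic Structural Variant Integration and Hi-C
    Junction Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates somatic structural variant (SV) call sets from
    multiple sequencing platforms and callers into a consensus call set:
    size-class splitting, windowed breakpoint merging, tumor-normal
    subtraction, reciprocal size-similarity clustering, per-tool and
    per-platform frequency scoring with high-confidence selection, and
    orthogonal-validation matching. Also implements a Hi-C contact-matrix
    rearrangement detector based on a Poisson quadrant z-statistic with
    exponential-kernel breakpoint refinement and quadrant-coverage event
    classification, plus a synthetic-data generator (truth SV sets,
    emulated multi-caller outputs, Hi-C matrices, purity/depth titrations)
    and evaluation utilities (recall/precision, cross-platform relative
    sensitivity, purity-depth sensitivity curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    igraph,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
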
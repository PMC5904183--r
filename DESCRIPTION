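Package: stiffscape
Title: Matrix-Stiffness Mechanoresponse Analysis for Lymphatic Endothelial Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how extracellular-matrix stiffness shapes
    lymphatic endothelial cell (LEC) biology. Implements a stepwise
    probe-level fold-change filter for exon-array transcriptomes (expression
    floor, per-probe log2 fold-change thresholds, a minimum-probe gene rule,
    bidirectional-gene exclusion), assessment of siRNA-dependent regulation
    on previously identified probe sets, and cross-stimulus gene-set
    comparison; Hertz-model analysis of AFM force-indentation curves with a
    square-pyramidal tip (deflection-sensitivity calibration, baseline and
    slope correction, contact-point and modulus fitting, per-region
    aggregation); and standard image-quantification formulas (corrected
    total cell fluorescence, nuclear circularity, nuclear/cytoplasmic
    intensity split, object counting). Synthetic-data generators with
    recorded ground truth make every stage testable without external
    downloads, and a pipeline runner orchestrates end-to-end analyses from
    a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
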
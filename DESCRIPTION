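Package: nucleotorus
Title: Quantification of Toroidal Nucleoid Organization in Widened Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Per-cell image quantification of chromosome organization in
    shape-widened Escherichia coli whose nucleoid adopts a toroidal (or,
    after failed decatenation, figure-eight) conformation. Provides cell
    segmentation from phase contrast, fluorescence thresholding, central
    ridge (backbone) tracing with topology classification, contour length
    and FWHM width morphometry, Feret diameters of SMC (MukBEF) clusters,
    intensity-overlap colocalization, a per-area DNA compaction ratio,
    diffraction-limited ori/ter focus detection with ploidy
    classification, an arm-asymmetry statistic around the replication
    origin, circular-genome peak-window analysis, population statistics
    with one-way ANOVA significance conventions, and a synthetic
    multi-channel image generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
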
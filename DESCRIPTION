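Package: myofuse
Title: Automated Quantitation of Myoblast Fusion from Double Fluorescent
    Labeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies myoblast differentiation from paired fluorescence
    images in which the cytoplasm and the nucleus carry separate labels.
    Detects nuclei as sub-pixel blob centroids in the nucleus channel,
    segments elongated myotube fibers in the cytoplasm channel, assigns
    nuclei to fibers, and computes the fusion index (the percentage of
    nuclei inside fibers holding three or more nuclei), nuclei counts,
    fiber-size summaries and object contrast. Aggregates per-field results
    into per-condition time courses and compares conditions with one-way
    ANOVA followed by Bonferroni-adjusted pairwise tests. Includes a
    synthetic-scene simulator with exact ground truth that emulates
    double-labeled C2C12 cultures over a differentiation time course,
    including drug-exposure schedules and autofluorescent scaffold
    background, used to validate the whole pipeline end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: CellBiology, CellBasedAssays, Visualization, Segmentation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
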
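Package: HAbrush
Title: Quantitative Analysis of Enzymatically Grown Hyaluronan Polymer Brushes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative analysis of giant hyaluronan (HA)
    polymer brushes grown in situ by surface-immobilized HA synthase.
    Implements extraction of brush concentration profiles and heights from
    confocal z-stacks (microsphere segmentation, azimuthal cone averaging,
    background-referenced edge detection, particle-exclusion height),
    solid-state nanopore molecular-weight distribution analysis (resistive
    pulse detection, event charge deficit, calibration to molecular weight),
    biofilm biovolume quantification by voxel counting, and the closed-form
    polymer-brush physics linking molecular weight, dry brush thickness,
    grafting density and brush regime. A synthetic-data module generates
    confocal stacks and nanopore current traces with known ground truth so
    every stage of the pipeline can be validated without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    signal,
    minpack.lm,
    data.table,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
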
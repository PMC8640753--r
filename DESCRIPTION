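Package: rhizolight
Title: Light-Sheet Mesocosm Imaging and Rhizosphere Colonization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for light-sheet fluorescence microscopy of
    plant roots growing in transparent soil mesocosms. Provides a seeded
    synthetic-mesocosm phantom generator (particle packing, elongating root,
    pulsatile bacterial density field) rendered through a 45-degree scan
    forward model; volume reconstruction by shear correction, mode-based
    flat-field estimation, Richardson-Lucy deconvolution with a light-sheet
    point spread function and Laplacian-pyramid tile stitching; segmentation
    of root and pore space with local-thickness pore sizing; and quantification
    of bacterial colonization via fluorescence-to-cell-density calibration,
    distance maps, indicator tables and colonization kinematics diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
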
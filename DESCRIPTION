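Package: axocarto
Title: Whole-Brain Axon Cartography on Synthetic Light-Sheet Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling long-range axonal projections in cleared
    whole mouse brains imaged by light-sheet fluorescence microscopy.
    Provides volume input/output (TIFF stacks and NRRD), cube extraction,
    tiling and stitching; automated voxel-level axon annotation by
    difference-of-Gaussians binarization, fragment connection, 3D
    topology-preserving skeletonization and unified-thickness dilation;
    volumetric training-pool augmentation (CutMix, background histogram
    matching, local contrast enhancement and standard geometric and
    photometric operators); volumetric and centerline-aware segmentation
    metrics (Dice, ClDice, ClPrecision, ClRecall), region-wise Dice
    reporting and landmark deviation; the full family of segmentation,
    style-transfer, multiview semi-supervised and registration loss
    functions as pure numeric functions; desk-scale multi-constraint
    multiscale 3D registration (rigid, affine and deformable stages by
    direct optimization on an image pyramid); and region-wise axon density
    quantification with hierarchical rollups and heatmaps. Synthetic
    generators for axon cubes, artifact cubes and phantom brains with
    exact ground truth make the whole pipeline testable without any
    external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    tiff,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    yaml
Config/testthat/edition: 3
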
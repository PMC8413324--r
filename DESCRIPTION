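Package: CortexMorph
Title: Serial-Section 3D Morphometry and Columnar Spatial Statistics for
    Cortical Neurons
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for serial-section light
    microscopy of cortical tissue: biopsy-placement sampling, section
    detection and rigid stack alignment, segmentation validation metrics,
    3D reconstruction of cells with voxel morphometrics (volume, surface
    area, sphericity, maximum Feret diameter, orientation), Gaussian
    mixture classification of pyramidal versus non-pyramidal cells,
    nucleator stereology for 2D size estimation, and detection of columnar
    spatial organization of cell centroids with the cylindrical K-function
    and extreme-rank-length global envelope tests.  A synthetic-scene
    generator renders image stacks of ellipsoidal somata with anisotropic
    voxels so that every stage can be exercised and calibrated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
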
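Package: histreg
Title: Multimodal Histological Image Registration with Annotation Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for pairwise registration of multimodal
    histology images (e.g. brightfield H&E against non-linear optical
    microscopy). Provides a plugin architecture for registration algorithms
    with a fixed eight-key result contract, reference feature-based plugins
    (multi-scale corner detection with SIFT-like and binary descriptors,
    ratio-test matching, robust homography estimation), transfer of COCO
    instance annotations between modalities via the estimated homography,
    conversion of mask images and multichannel mask arrays to COCO polygons
    by marching-squares contour extraction, registration quality metrics
    (SSD, cross-correlation, mutual information, target registration error),
    tiled multiresolution image pyramids, composite QC views (chessboard,
    line matching, feature and annotation overlays), and batch project
    management with a command-line interface. A synthetic fixture generator
    produces multimodal pairs with known ground-truth transforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    grDevices,
    jpeg,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
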
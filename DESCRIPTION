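Package: liverseg
Title: Two-Stage Liver and Liver-Lesion Segmentation from CT with an
    Ensemble of Convolutional Backbones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-stage semantic-segmentation system for liver and
    liver-lesion delineation in computed-tomography examinations. Four
    image-classification backbones (ResNet152, ResNeXt101-32x8d,
    DenseNet201, InceptionV3) are re-built as single-channel feature
    extractors and combined with an atrous-spatial-pyramid-pooling
    segmentation head; the four per-network masks are merged by a
    trainable weighted decision-fusion module. The package also provides
    the surrounding plumbing: Hounsfield-unit windowing, liver-masked
    volume-of-interest extraction, CLAHE contrast enhancement,
    connected-component mask post-processing, Dice evaluation in global
    and per-case form, NIfTI and DICOM input, RGB-overlay DICOM output,
    and a synthetic CT phantom generator so the whole pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
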
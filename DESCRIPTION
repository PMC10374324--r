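Package: grapedet
Title: Attention-Augmented YOLO v4 Detection of Grape Bunches in Unstructured Orchards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-stage detector for grape bunches in unstructured orchard
    scenes: a CSPDarkNet-53 backbone refined by the parameter-free SimAM
    attention block, a path-aggregation neck with fast-normalized weighted
    fusion and jump connections, and YOLO prediction heads at three scales.
    Includes the composite training loss (focal-modulated binary cross-entropy
    for confidence and class, Complete-IoU box regression), IoU-metric K-means
    anchor clustering, the box-aware dataset augmentation operators
    (brightness, Gaussian blur, affine, mirror, raindrop, fog), conversion
    between YOLO text labels and Pascal VOC XML, the full
    precision/recall/F1/AP evaluation stack, a two-stage training schedule
    with cosine-annealed learning rates, and a seeded synthetic-orchard scene
    generator so the whole pipeline is testable without external data. The
    network layers (convolution, batch normalization, Mish, weighted fusion)
    run on a small reverse-mode automatic-differentiation engine built on
    BLAS matrix products.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    xml2,
    yaml,
    jsonlite,
    png,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
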
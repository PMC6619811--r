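Package: planktonseg
Title: Adaptive Segmentation, Enhancement and Classification of In Situ
    Plankton Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying and enumerating
    plankton in dark-field in situ imagery. Frames are routed by a
    mean-signal-to-noise-ratio contrast statistic to either
    single-pixel sliding-window Sauvola binarization (low contrast) or
    maximally stable extremal regions (high contrast); candidate
    regions of interest are cleaned by a spatial-domain
    breakpoint-connection rule, enhanced by a boundary-parameter
    grayscale transform that suppresses background, expanded by
    class-rarity rotation/mirror recipes and multi-level contrast
    augmentation, and classified by a one-vs-one multi-class linear
    support vector machine with probability voting over histogram of
    oriented gradients features or pluggable embeddings. A seeded
    synthetic scene generator with ground-truth masks makes the whole
    pipeline testable without any real imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
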
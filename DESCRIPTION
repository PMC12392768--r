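Package: dentalarch
Title: Tooth Sequencing, Pose Standardization and FDI Relabeling for Intraoral Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Algorithmic toolkit for full- and partial-arch intraoral scan
    (IOS) processing: partial-arch crop augmentation, occlusal-plane pose
    standardization with its alignment loss functions, a Gaussian
    tooth-pair-offset model combined with minimum-cost dynamic programming
    for FDI tooth numbering, and a complete segmentation/labeling metric
    suite (tooth F1, tooth Dice, macro-F1, macro-IoU, TLA/TSA/TIR).
    Includes a seeded synthetic dental arch generator and a noise-injecting
    mock predictor so the whole pipeline is testable without real scans or
    trained networks. Reads and writes PLY meshes with Teeth3DS-style JSON
    annotation sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
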
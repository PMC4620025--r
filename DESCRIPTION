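Package: topocode
Title: Topographic Sparse Coding for Cell-Cycle Phase Recognition in Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dictionary learning with a smoothed, grouped (topographic) L1
    penalty, optimized by alternating mini-batch gradient descent, embedded in
    a complete pipeline for recognizing cell-cycle phases (interphase,
    prophase, metaphase, anaphase) in grayscale time-lapse microscopy frames.
    Provides nucleus segmentation by Otsu binarization and seeded watershed,
    four per-nucleus feature extractors (resampled raw intensity, oriented
    gradient histograms, Gabor-bank texture, dense gradient descriptors),
    sparse-code feature learning, one-vs-rest RBF-kernel support vector
    classification, confusion-count evaluation metrics, and a synthetic frame
    generator so every stage is testable without real imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    tiff,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    rlang,
    yaml,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
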
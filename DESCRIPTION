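Package: spiralAD
Title: Hybrid Spiral-Image Analysis of Online Handwriting for Early
    Alzheimer's Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of digitized Archimedes-spiral drawings for
    early-stage Alzheimer's disease screening. Online pen recordings
    (position, pressure, azimuth, altitude at 125 Hz, including in-air
    trajectory) are rasterized into "hybrid" grayscale trajectory images
    that encode one dynamic parameter (pressure, altitude, velocity or
    acceleration) pointwise as an ink level. Off-the-shelf features are
    read from tapped layers of an AlexNet-architecture convolutional
    network, per-parameter RBF-SVM experts are trained under a balanced
    subject-resampling protocol with grid-searched 5-fold cross-validation,
    and expert decisions are fused by majority vote. A synthetic spiral
    cohort generator with a tunable class effect size stands in for
    clinical data, and a configuration-driven pipeline reproduces the
    full experiment grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    kernlab,
    png,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
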
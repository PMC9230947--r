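Package: facemark
Title: Flexible Upper-Face Landmark Detection and Emotion Recognition for
    Masked Faces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects flexible facial landmarks on the unoccluded upper half of
    a masked face by sampling pixel intensities along an infinity-shaped
    (figure-eight) parametric curve anchored at a projection-profile seed
    point, describes each landmark with a compact histogram-of-oriented-
    gradients descriptor, and classifies the resulting landmark sequences
    into emotion categories with a small convolutional plus LSTM network.
    Includes a synthetic upper-face generator with ground-truth boundary
    masks so the whole pipeline is testable without external face datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
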
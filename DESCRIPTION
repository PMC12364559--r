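Package: motionaug
Title: Movement-Based Image Augmentation for Ecological Object Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies movement in ecological monitoring video and camera-trap
    burst sequences (three-frame differencing, background subtraction via frame
    averaging, a per-pixel KNN foreground classifier, and dense optical flow with
    magnitude/direction encoding) and folds the resulting motion layers back into
    ordinary RGB images by channel replacement or PCA colour compression, so that
    any off-the-shelf object detector can be trained on movement-augmented data.
    Includes a synthetic scene generator with exact ground-truth bounding boxes,
    YOLO-format annotation and dataset I/O, PASCAL-style mean-average-precision
    evaluation, and a tuning workflow that selects augmentation parameters on a
    validation split.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
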
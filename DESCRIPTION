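Package: depthpose
Title: Marker-Less Body-Joint Detection Pipelines for Depth Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for marker-less human body-joint detection in depth
    images from a fixed depth camera, aimed at instrumented mobility
    assessments such as the timed "up & go" test. Provides a pinhole camera
    model for projecting point clouds to depth images and back, a
    point-cloud preprocessing pipeline (moving-least-squares smoothing,
    RANSAC floor-plane removal, lateral and centre-of-mass depth crops,
    gray-value normalization, aspect-preserving crop and scale with an
    invertible coordinate transform), Gaussian target-heatmap generation
    and the joints mean-squared-error loss, heatmap decoding with
    ROC-optimal visibility thresholding, 3D keypoint localization with
    per-axis spatial-error summaries, the COCO-keypoint evaluation
    suite (object keypoint similarity, AP/AR family, confusion metrics,
    per-joint sensitivity/specificity/F1), and a synthetic labeled
    depth-scene generator with a pluggable predictor contract so every
    stage is testable without recorded study data.
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
    grDevices,
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
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
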
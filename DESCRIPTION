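Package: boxfuse
Title: Multi-Observer Bounding-Box Annotation Fusion and Detection Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building consensus ground truth from bounding-box
    annotations drawn independently by several observers, and for evaluating
    object detectors (or the observers themselves) against such ground truth.
    Annotations on one image are grouped by intersection-over-union, each box
    in a group is represented by axis-aligned Gaussian densities, and the
    consensus box is extracted as a relative level set of the equal-weight
    Gaussian mixture density, with a majority-then-severity vote for the
    class label. Evaluation follows the PASCAL VOC protocol: per-class
    all-point interpolated average precision, F1-score and false negative
    rate at a configurable IoU threshold, with bias-corrected and
    accelerated (BCa) bootstrap confidence intervals resampled at the image
    level. Includes a synthetic multi-rater scene generator, k-fold and
    grouped split utilities, and readers/writers for CSV and COCO-style JSON
    annotation files. Developed around dental radiograph (bitewing) caries
    annotation, where lesions are graded by severity, but applicable to any
    axis-aligned box annotation task.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
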
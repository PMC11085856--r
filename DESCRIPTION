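Package: gazefuse
Title: Automatic Fixation Annotation for Mobile Eye-Tracking by Fusing
    Segmentation and Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates fixations from head-worn eye-tracker recordings with
    the object being looked at. Detects fixations in normalized gaze streams
    with the dispersion-threshold (IDT) algorithm, maps each fixation onto a
    scene-video frame, and fuses two complementary per-frame perception
    outputs -- a dense semantic-segmentation label map and a set of labeled
    bounding boxes with confidences -- by selecting, among the boxes that
    contain both the fixation point and the fixated mask, the box with the
    highest mask coverage. A configurable rule cascade resolves the two
    labels into one, optionally merging related classes, and an evaluation
    module scores annotations against manual ground truth with accuracy,
    per-class precision/recall/F1 and macro/weighted averages. A fully
    deterministic synthetic scene and gaze generator makes the entire
    pipeline testable without pretrained models or recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    png,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
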
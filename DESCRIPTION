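Package: toothnum
Title: Post-Processing and Evaluation for Tooth Detection and Numbering in
    Dental Periapical Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning noisy per-tooth object-detection output on
    dental periapical films into clinically consistent FDI tooth numbers.
    Implements cross-label suppression of excessively overlapping boxes,
    a geometric gap classifier that predicts the number of missing teeth
    (0-3) between adjacent boxes, similarity-weighted template matching
    against the 16-slot FDI arrangement sequences, and a detection
    evaluation suite (greedy IOU matching, detection and numbering
    precision/recall, mean IOU, 11-point interpolated mAP). A synthetic
    film and detection-noise generator makes the whole pipeline testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
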
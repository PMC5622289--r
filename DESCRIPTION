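Package: slidestitch
Title: Stitching Microscope Fields of View into Browser-Viewable Virtual Slides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles whole-slide images ("virtual slides") from sequences of
    overlapping microscope fields of view captured with uncalibrated consumer
    cameras. Provides SURF-style keypoint detection with per-layer adaptive
    thresholding, prior-guided selective keypoint matching, self-calibration
    of unknown lens distortion with a high-order polynomial model fitted from
    pooled pairwise matches, translation-graph global alignment, feathered
    mosaic rendering with tiled-pyramid export, a client-side scan tracker
    that emits operator guidance from a finite-state machine, a deterministic
    ground-truthed synthetic scan generator used as the test substrate, and
    slide-level diagnostic agreement tabulation (accurate / low-sensitivity /
    low-specificity) with cross-rater averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
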
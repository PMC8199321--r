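Package: handstates
Title: Discrete Semantic States of Hand Motion Primitives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments the continuous motion of hand and wrist motion
    primitive units (one joint, one motion form) into discrete semantic
    states using constant-stimuli psychophysics: same/different judgments
    are aggregated into difference degrees, probit-transformed, fitted by
    least squares against joint angle, and thresholded at the
    just-noticeable-difference criterion Z = 0.67. Expression data from
    gesture performers validate and adjust the perceptual boundaries
    (inter-rater ICC, outlier-robust feature angles, boundary adjustment,
    range widening, merging of paired primitives). A calibration module
    fits affine mappings between ruler-verified joint angles and the
    readings of an optical hand tracker and transfers segmentations into
    device space. Poses are encoded to and decoded from discrete semantic
    codes. A synthetic-data module simulates observers, performers and
    devices for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
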
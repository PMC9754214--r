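Package: midribr
Title: Correction, Smoothing and Phenotyping of 3D-Digitized Leaf Midrib Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing ordered 3D digitizer key points of maize
    stalks and ear-leaf midribs. Implements positive-direction correction of
    the stalk axis, equidistant interpolation, cubic B-spline densification,
    and a curvature-constrained iterative smoother that corrects fluctuating
    key points; normalizes the midrib direction plane; extracts fifteen
    multi-dimensional (0D-3D) midrib shape traits; classifies midribs into
    seven architectural types; and ships a seeded synthetic digitizer
    simulator for end-to-end validation and parameter-recovery benchmarks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
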
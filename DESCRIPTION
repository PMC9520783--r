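Package: opmcoreg
Title: Co-Registration of On-Scalp OPM-MEG Sensor Arrays with Structural MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Maps optically pumped magnetometer (OPM) MEG sensor positions and
    orientations from the helmet-design frame, through a fiducial-based head
    frame, into the MRI frame, for three digitization devices: an
    electromagnetic stylus digitizer, a structured-light scanner, and a laser
    scanner. Provides rigid Kabsch alignment, trimmed iterative closest point
    (ICP) surface registration, HSV colour-marker extraction from coloured
    point clouds, PLY mesh input/output, sensor depth correction, registration
    error reporting, and a seeded synthetic head/helmet phantom generator with
    known ground-truth transforms for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    pracma,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
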
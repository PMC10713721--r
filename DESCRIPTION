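Package: migrascreen
Title: High-Throughput Immune-Cell Migration Screening with an Array
    Video Microscope
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis toolkit for array-microscope
    migration screens of fast-moving immune cells such as neutrophils.
    Provides closed-form optics and sensor-bandwidth budgeting, a
    simulator of the acquisition control loop (sharpness scoring,
    ping-pong frame buffering, autofocus modes, focus-position maps and
    XYZ stage scheduling against the 8 s frame interval), a
    ground-truthed synthetic data generator (persistent-random-walk cell
    tracks, rendered time-lapse stacks, defocus stacks and whole
    compound screens with planted hits), Earth Mover's Distance
    single-cell tracking via an exact min-cost-flow transportation
    solver, per-track and per-well motility statistics with
    control-normalized hit calling and compound classification, and a
    frame-pair evaluation scheme for tracker correctness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    clue,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
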
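Package: fuccitrackr
Title: Cell-Cycle Track Fusion and Tissue Kinematics for FUCCI Time-Lapse Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless analysis of two-channel FUCCI (fluorescent
    ubiquitination-based cell cycle indicator) time-lapse movies of dense,
    collectively migrating cell monolayers. Provides a synthetic FUCCI movie
    simulator with full ground truth, classical nuclear segmentation, LAP-style
    frame-to-frame tracking with gap closing, automatic pairing of red
    (cdt1-reporter) and green (geminin-reporter) tracks into continuous
    single-cell cell-cycle tracks with a user-independent G1-to-S transition
    criterion, and tissue-level analysis: Voronoi cell areas, phase-count time
    series, and an Eulerian velocity field sampled on a triangular lattice.
    All results are tidy tibbles designed for piped workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    clue,
    deldir,
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
    tiff,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
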
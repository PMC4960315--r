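Package: nichetrackr
Title: Single-Cell Tracking and Niche-Interaction Analysis for Intravital
    Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how individual haematopoietic cells interact
    with vascular and endosteal niche domains in intravital time-lapse movies of
    the bone marrow. The pipeline covers lateral drift correction by
    cross-correlation, cell detection (median filter, threshold, connected
    components), particle tracking with gap closing, Euclidean distance
    transforms of annotated niche regions, classification of cell positions
    into contact/proximal/distal zones with hysteresis, segmentation of
    interaction periods with transient merging and duration classes, and
    per-cell and population metrics (velocities, normalized displacement, time
    fractions, interaction incidence, occupancy maps). A synthetic-movie
    generator provides exact ground truth (drift, tracks, interaction events)
    so that every stage can be validated without microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
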
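Package: tracker3d
Title: Three-Dimensional Single-Cell Tracking in Light-Sheet Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks single fluorescent cells in three dimensions from
    time-lapse z-stacks of light-sheet fluorescence microscopy images.
    The pipeline corrects uneven illumination (vignetting), rigidly aligns
    stacks to a global reference frame, reduces each stack to a 2D
    maximum-intensity projection (or an extended-depth-of-field image),
    detects and links cells in 2D, and recovers the axial coordinate of
    each tracked cell per time point from the intensity profile along z.
    Quantitative motility measures (path length, distance from origin,
    speed, straightness) are computed in physical units and exported as
    CSV, XLSX and JSON. A synthetic generator simulates cells moving on
    the surface of a spherical microcarrier and renders them as noisy
    fluorescence z-stacks, so that every stage of the pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    EBImage,
    clue,
    igraph,
    jsonlite,
    zip,
    withr,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    readxl,
    yaml,
    optparse
Config/testthat/edition: 3
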
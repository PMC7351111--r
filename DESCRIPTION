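Package: recruitkin
Title: Quantification of DNA-Damage Recruitment Kinetics from Laser
    Microirradiation Imaging
Version: 0.1.0
Authors@R: person("recruitkin", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify the recruitment of fluorescently tagged
    repair proteins to laser-microirradiated stripes in live-cell imaging:
    per-cell relative stripe brightness Sx = (Ax-B)/(Cx-B), cross-cell
    aggregation with SEM, additive normalization to the pre-irradiation
    frame, and per-timepoint condition comparison by Student's t test.
    Companion statistics for nuclear-foci burden (percentage of nuclei with
    more than a threshold number of foci, from Laplacian-of-Gaussian
    detection on z-stack projections) and clonogenic survival curves
    (plating-efficiency normalized surviving fractions) are included,
    together with a synthetic fluorescence-microscopy generator (stripe
    movies, foci z-stacks, colony counts) with known ground truth, minimal
    multi-page TIFF and polygon-ROI I/O, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
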
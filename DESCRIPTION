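Package: parabtrack
Title: Single-Cell Analysis of ParA/ParB Partitioning-Protein Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for time-lapse fluorescence measurements of
    the ParABS chromosome-partitioning system in rod-shaped bacteria.
    Detects ParB foci on axial fluorescence profiles with noise-perturbation
    validation, links foci into tracks across frames and divisions, computes
    mean-squared-displacement curves of focus-to-ParA-maximum distances with
    power-law (anomalous diffusion) fits, classifies focus velocities as
    moving toward, with, or away from the ParA maximum, and quantifies
    asymmetric ParA inheritance between sibling cells. Includes a
    ground-truthed synthetic-lineage simulator (exponentially growing,
    asymmetrically dividing rod cells with fractional-Gaussian-noise focus
    motion) so every stage is testable without raw microscopy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
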
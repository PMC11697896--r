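Package: aqueduct
Title: Cerebral Aqueduct Hydraulic Resistance and Pressure Difference from MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for non-invasive quantification of the
    pressure difference across the cerebral aqueduct. Builds a finite-element
    Poiseuille model of the aqueduct lumen from high-resolution morphological
    MRI (maximum-intensity projection, gradient-based binarization,
    centerline and per-element diameter extraction, cumulative hydraulic
    resistance with a 95% endpoint rule), processes real-time phase-contrast
    velocity series into a continuous flow curve (frequency-domain ROI
    detection, velocity de-aliasing, stationary-tissue background
    correction, cardiac-cycle segmentation, 32-point ensemble averaging with
    95% limits of agreement), decomposes flow into cardiac-driven and
    breathing-driven components, and combines resistance and flow into
    trans-aqueductal pressure differences. Includes synthetic phantom
    generators with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    mgcv,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
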
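Package: noarsa
Title: Intensity-Based Nonoverlapping-Area 2D-3D Registration for Model-Based
    Radiostereometric Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers the six-degree-of-freedom pose of a prosthesis surface
    mesh from a calibrated stereo pair of radiographs by rendering binary
    silhouette digitally reconstructed radiographs (DRRs) and minimizing the
    nonoverlapping area (NOA) between real and reconstructed segmentations
    with a coarse-to-fine Levenberg-Marquardt scheme using central-difference
    Jacobians. Includes direct linear transformation (DLT) stereo calibration
    and triangulation, drop-out masking of unreliable image regions, grayscale
    (histogram-equalized) registration, a synthetic phantom generator with a
    biplanar calibration cage, and an in silico evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
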
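Package: mrlqa
Title: Quality-Assurance Analyses for MR-Guided Linear Accelerators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Machine quality-assurance computations for ring-gantry MR-linacs
    of the Elekta Unity type: sub-pixel ballbearing localization on megavoltage
    portal images with background subtraction and FWHM peak finding, minimax
    (Chebyshev) fitting of the MV radiation isocentre from back-projected beam
    axis lines, gamma-index comparison of 2-D dose maps with global or local
    normalization and low-dose suppression, and the magnetic-field-aware
    reference-dosimetry chain (TPR beam-quality ratios, TRS-398 influence
    quantities, magnetic-field correction factors, anterior-coil attenuation
    statistics). A synthetic phantom/image simulator with known ground truth
    exercises every analysis without access to a machine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    png,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
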
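Package: mbkit
Title: Contractile Kinetics and Myofibrillar Structure Quantification for
    Micropatterned Cardiac Muscle Bundles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis platform for micron-scale two-dimensional cardiac
    muscle bundles (2DMBs): subpixel cross-correlation displacement tracking
    of brightfield contraction movies, fractional-shortening waveform and
    beat-kinetics extraction, sarcomere-unit segmentation with orientation
    dispersion fitting, myofibrillar-bundle density quantification from
    F-actin images, a layered elastic substrate-coupling model, seeded
    synthetic-data generators with exact ground truth, and reproducibility
    and power statistics for contractile assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    graphics,
    jsonlite,
    Matrix,
    minpack.lm,
    signal,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
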
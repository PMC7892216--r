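Package: filmhnn
Title: Radiochromic Film Dose Calibration with a Hierarchical Neural Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibration of EBT3 radiochromic film for radiotherapy dosimetry.
    Extracts midline depth profiles from prescan/postscan flatbed TIFF scans,
    computes net optical density, raw pixel-value and inverse-transmittance
    features, and maps them to delivered dose either through the conventional
    red-channel net-optical-density power-law fit or through a seven-subnet
    hierarchical neural network trained against delivered dose. A cubic refit
    transfers the trained network to film lots outside the training lot, and
    verification protocols quantify residual errors under film aging and
    lot-to-lot sensitivity variation. A synthetic film-response simulator with
    lot sensitivity shifts, shelf-age drift and scanner noise makes the whole
    pipeline exercisable without physical films.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
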
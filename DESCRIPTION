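Package: polsmv
Title: Single-Shot Hyperspectral Imaging with Polarisation-Based Spectral
    Modulation Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward modelling and analysis for hyperspectral imaging with
    Lyot-type polarisation interferometers read out by a polarisation-resolving
    (division-of-focal-plane) camera. Provides seeded generators for synthetic
    hyperspectral scenes, the cosine-in-frequency Lyot transmission model, the
    single-shot four-channel forward models with a Jones-calculus oracle, a
    polarisation-mosaic sensor model with shot and read noise, generalised
    spectral modulation vector (SMV) computation, instrument-response
    calibration from narrowband sweeps, retardance fitting, and SMV-space
    classification, linear unmixing and pseudocolour synthesis.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    pracma,
    stats,
    tiff,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
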
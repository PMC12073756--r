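Package: scanHSI
Title: Hyperspectral Imaging by Linear Variable Bandpass Filter Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and full reconstruction pipeline for a
    low-cost hyperspectral imaging (HSI) system built from a high frame
    rate RGB consumer camera and a linearly variable spectral bandpass
    filter (LVSBPF) swept across the field of view. Provides a physics
    based scene simulator with known ground truth, radiometric gamma
    linearization, row-shift estimation and de-shearing of the raw video
    stack, frame-to-wavelength mapping anchored on grey-plate onsets,
    channel trimming and summation, reflectance calibration against a
    grey reference plate, Savitzky-Golay denoising and spectral binning
    to a 45-band reflectance hypercube, plus a one-dimensional
    convolutional neural network for per-pixel classification of
    macroalgae spectra and segmentation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'specs.R'
    'wavelength.R'
    'calibrate.R'
    'cube.R'
    'config.R'
    'gamma.R'
    'io-container.R'
    'io-envi.R'
    'library.R'
    'metrics.R'
    'cnn.R'
    'train.R'
    'shift.R'
    'pipeline.R'
    'cli.R'
    'simulate.R'
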
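# S4 class definitions for the scanning-filter HSI pipeline.

#' @import methods
NULL

.CHANNELS <- c("R", "G", "B")

#' Linearly variable spectral bandpass filter specification
#'
#' Describes the optical filter swept across the camera's field of view: its
#' physical length and the linear gradients of band center wavelength (CWL)
#' and full width at half maximum (FWHM) along that length. The passband at a
#' fractional position `p` along the filter is modeled as a Gaussian with
#' center `cwlStart + p * (cwlEnd - cwlStart)` and width
#' `fwhmStart + p * (fwhmEnd - fwhmStart)`.
#'
#' @slot lengthMM physical filter length in mm.
#' @slot cwlStart,cwlEnd center wavelength (nm) at the two filter ends.
#' @slot fwhmStart,fwhmEnd FWHM bandwidth (nm) at the two filter ends; must
#'   be positive.
#' @slot peakTransmittance peak in-band transmittance, in `[0, 1]`.
#' @seealso [FilterSpec()], [filterTransmission()]
#' @export
setClass("FilterSpec",
  representation(
    lengthMM = "numeric",
    cwlStart = "numeric", cwlEnd = "numeric",
    fwhmStart = "numeric", fwhmEnd = "numeric",
    peakTransmittance = "numeric"
  )
)

setValidity("FilterSpec", function(object) {
  msg <- character()
  if (object@lengthMM <= 0) msg <- c(msg, "lengthMM must be positive")
  if (object@cwlEnd == object@cwlStart)
    msg <- c(msg, "cwl gradient must be strictly monotone (cwlStart != cwlEnd)")
  if (object@fwhmStart <= 0 || object@fwhmEnd <= 0)
    msg <- c(msg, "FWHM must be > 0 at both filter ends")
  if (object@peakTransmittance < 0 || object@peakTransmittance > 1)
    msg <- c(msg, "peakTransmittance must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Camera gamma curve
#'
#' Monotone mapping between normalized linear incident power (in `[0, 1]`)
#' and 8-bit digital counts for one RGB channel, represented by measured
#' knots. Fitted curves interpolate the knots with a monotone (Hyman) cubic
#' spline after isotonic projection; see [fitGamma()].
#'
#' @slot channel one of `"R"`, `"G"`, `"B"`.
#' @slot knots two-column matrix `(power, count)`, powers ascending in
#'   `[0, 1]`, counts non-decreasing, first knot `(0, 0)`.
#' @seealso [fitGamma()], [gammaForward()], [gammaInverse()],
#'   [linearizeStack()]
#' @export
setClass("GammaCurve",
  representation(channel = "character", knots = "matrix")
)

setValidity("GammaCurve", function(object) {
  msg <- character()
  k <- object@knots
  if (!object@channel %in% .CHANNELS)
    msg <- c(msg, "channel must be one of R, G, B")
  if (ncol(k) != 2 || nrow(k) < 2)
    msg <- c(msg, "knots must be a (power, count) matrix with >= 2 rows")
  else {
    if (is.unsorted(k[, 1], strictly = TRUE))
      msg <- c(msg, "knot powers must be strictly increasing")
    if (is.unsorted(k[, 2]))
      msg <- c(msg, "knot counts must be non-decreasing")
    if (k[1, 1] != 0 || k[1, 2] != 0)
      msg <- c(msg, "first knot must be (0, 0)")
    if (min(k[, 1]) < 0 || max(k[, 1]) > 1)
      msg <- c(msg, "knot powers must lie in [0, 1]")
    if (max(k[, 2]) > 255)
      msg <- c(msg, "knot counts must be <= 255")
  }
  if (length(msg)) msg else TRUE
})

#' Camera specification
#'
#' Acquisition parameters of the RGB video camera behind the scanning
#' filter: frame geometry, frame rate, bit depth, per-channel gamma encoding
#' and per-channel spectral sensitivity (modeled as Gaussian response curves
#' over wavelength).
#'
#' @slot frameRate frames per second (default 240).
#' @slot bitDepth bits per channel (default 8).
#' @slot rows,cols sensor dimensions in pixels.
#' @slot gamma named list of three [GammaCurve-class] objects (`R`, `G`,
#'   `B`) applied by the sensor when encoding counts.
#' @slot sensMean,sensSd named numeric vectors (`R`, `G`, `B`): center (nm)
#'   and width (nm) of each channel's Gaussian spectral sensitivity.
#' @slot gain linear scaling from integrated spectral signal to the
#'   normalized `[0, 1]` sensor input; `NA` emulates auto-exposure: the
#'   brightest signal the scene produces is scaled to 0.95, just below
#'   saturation (a fixed exposure shared across renders requires an
#'   explicit gain).
#' @seealso [CameraSpec()], [renderScan()]
#' @export
setClass("CameraSpec",
  representation(
    frameRate = "numeric", bitDepth = "numeric",
    rows = "integer", cols = "integer",
    gamma = "list",
    sensMean = "numeric", sensSd = "numeric",
    gain = "numeric"
  )
)

setValidity("CameraSpec", function(object) {
  msg <- character()
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (!object@bitDepth %in% c(8, 10, 12, 16))
    msg <- c(msg, "bitDepth must be one of 8, 10, 12, 16")
  if (object@rows < 4 || object@cols < 1)
    msg <- c(msg, "sensor must have >= 4 rows and >= 1 column")
  if (!identical(sort(names(object@gamma)), sort(.CHANNELS)))
    msg <- c(msg, "gamma must be a named list with entries R, G, B")
  else if (!all(vapply(object@gamma, inherits, logical(1), "GammaCurve")))
    msg <- c(msg, "gamma entries must be GammaCurve objects")
  for (s in c("sensMean", "sensSd")) {
    v <- slot(object, s)
    if (!identical(sort(names(v)), sort(.CHANNELS)))
      msg <- c(msg, paste(s, "must be named R, G, B"))
  }
  if (any(object@sensSd <= 0)) msg <- c(msg, "sensSd must be positive")
  if (!is.na(object@gain) && object@gain <= 0)
    msg <- c(msg, "gain must be positive (or NA for auto)")
  if (length(msg)) msg else TRUE
})

#' Scene specification for the forward simulator
#'
#' A synthetic flat scene imaged through the scanning filter: an integer
#' label map over the sensor grid (0 = neutral grey background plate),
#' per-class reflectance spectra as functions of wavelength, and the
#' illumination spectrum. Scenes made by [makeScene()] always keep grey
#' margin rows at the top and bottom of the frame; the reconstruction
#' pipeline uses them for shift estimation, onset detection and reflectance
#' calibration.
#'
#' @slot labelMap integer matrix (rows x cols); 0 is the grey plate.
#' @slot classNames character vector naming labels `1..K`.
#' @slot spectra named list of reflectance functions of wavelength (nm),
#'   one per entry of `classNames` plus `"grey"`; values must be in
#'   `[0, 1]`.
#' @slot illumination spectral radiance function of wavelength (relative
#'   units, non-negative).
#' @slot greyReflectance flat reflectance of the background plate
#'   (default 0.1).
#' @slot marginRows number of guaranteed grey rows at the top and bottom of
#'   the frame.
#' @seealso [makeScene()], [referenceSpectrum()], [renderScan()]
#' @export
setClass("SceneSpec",
  representation(
    labelMap = "matrix", classNames = "character",
    spectra = "list", illumination = "function",
    greyReflectance = "numeric", marginRows = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  lm <- object@labelMap
  if (!is.numeric(lm) || any(lm != round(lm)) || any(lm < 0))
    msg <- c(msg, "labelMap must contain non-negative integer labels")
  if (!any(lm == 0))
    msg <- c(msg, "label 0 (grey background plate) must be present: it is needed for calibration")
  k <- max(lm)
  if (k < 1) msg <- c(msg, "at least one non-background class is required")
  if (length(object@classNames) < k)
    msg <- c(msg, "classNames must name every label used in labelMap")
  need <- c("grey", object@classNames)
  if (!all(need %in% names(object@spectra)))
    msg <- c(msg, "spectra must contain an entry per class plus 'grey'")
  if (object@greyReflectance <= 0 || object@greyReflectance > 1)
    msg <- c(msg, "greyReflectance must be in (0, 1]")
  if (object@marginRows < 1 || 2 * object@marginRows >= nrow(lm))
    msg <- c(msg, "marginRows must leave interior rows free")
  lam <- seq(400, 700, by = 5)
  for (nm in intersect(need, names(object@spectra))) {
    r <- object@spectra[[nm]](lam)
    if (any(!is.finite(r)) || any(r < 0) || any(r > 1)) {
      msg <- c(msg, sprintf("reflectance of class '%s' must be finite and in [0, 1]", nm))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Scan specification
#'
#' Kinematics and noise of one full sweep of the filter across the field of
#' view.
#'
#' @slot nFrames frames per full sweep (the spectral sampling density;
#'   70-350 is the practical range, default 240).
#' @slot shiftSlope true row shift in frames per row: because the filter
#'   moves while every row sees a different lateral filter position, the
#'   same wavelength reaches row `y` a fraction `shiftSlope * y` of a frame
#'   later than row 0.
#' @slot noiseSd additive Gaussian sensor noise, in normalized linear
#'   intensity units, applied before gamma encoding.
#' @slot seed integer RNG seed making renders reproducible.
#' @seealso [ScanSpec()], [renderScan()]
#' @export
setClass("ScanSpec",
  representation(
    nFrames = "integer", shiftSlope = "numeric",
    noiseSd = "numeric", seed = "integer"
  )
)

setValidity("ScanSpec", function(object) {
  msg <- character()
  if (object@nFrames < 2) msg <- c(msg, "nFrames must be >= 2")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (!is.finite(object@shiftSlope)) msg <- c(msg, "shiftSlope must be finite")
  if (length(msg)) msg else TRUE
})

#' Raw scan stack
#'
#' The instrument's raw output: a 4-D stack of 8-bit video frames with
#' dimensions `(frame, row, col, channel)`, plus the acquisition metadata
#' that produced it. Simulated stacks also carry their [SceneSpec-class]
#' ground truth (`NULL` for imported real data).
#'
#' @slot counts integer array `(frame, row, col, channel)` in
#'   `[0, 2^bitDepth - 1]`.
#' @slot camera the [CameraSpec-class] used.
#' @slot scan the [ScanSpec-class] used.
#' @slot scene ground-truth [SceneSpec-class] or `NULL`.
#' @seealso [renderScan()], [readRawScan()], [linearizeStack()]
#' @export
setClass("RawScanStack",
  representation(
    counts = "array", camera = "CameraSpec", scan = "ScanSpec", scene = "ANY"
  )
)

setValidity("RawScanStack", function(object) {
  msg <- character()
  d <- dim(object@counts)
  if (length(d) != 4 || d[4] != 3)
    msg <- c(msg, "counts must be a 4-D (frame, row, col, channel=3) array")
  else {
    if (d[1] != object@scan@nFrames)
      msg <- c(msg, "frame dimension must equal scan nFrames")
    if (d[2] != object@camera@rows || d[3] != object@camera@cols)
      msg <- c(msg, "spatial dimensions must match the camera rows/cols")
  }
  if (!is.integer(object@counts))
    msg <- c(msg, "counts must be an integer array")
  else {
    mx <- 2^object@camera@bitDepth - 1
    rng <- range(object@counts)
    if (rng[1] < 0 || rng[2] > mx)
      msg <- c(msg, sprintf("counts must lie in [0, %d]", mx))
  }
  if (!is.null(object@scene) && !is(object@scene, "SceneSpec"))
    msg <- c(msg, "scene must be a SceneSpec or NULL")
  if (length(msg)) msg else TRUE
})

#' Linearized (and optionally de-sheared) scan stack
#'
#' Real-valued stack after gamma inversion: normalized linear intensities in
#' `[0, 1]` with a saturation mask, either still sheared (straight from
#' [linearizeStack()]) or monochromatic per frame after [deshearStack()].
#'
#' @slot values double array `(frame, row, col, channel)` in `[0, 1]`.
#' @slot saturated logical array of the same shape flagging saturated
#'   counts.
#' @slot camera,scan acquisition metadata (see [RawScanStack-class]).
#' @slot scene ground-truth [SceneSpec-class] or `NULL`.
#' @slot desheared `TRUE` once rows have been re-aligned to common filter
#'   positions.
#' @slot frameOffset 0-based source frame number of the first stored frame
#'   (non-zero after de-shearing drops boundary frames).
#' @seealso [linearizeStack()], [deshearStack()], [detectOnsets()]
#' @export
setClass("LinearScan",
  representation(
    values = "array", saturated = "array",
    camera = "CameraSpec", scan = "ScanSpec", scene = "ANY",
    desheared = "logical", frameOffset = "integer"
  )
)

setValidity("LinearScan", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 4 || d[4] != 3)
    msg <- c(msg, "values must be a 4-D (frame, row, col, channel=3) array")
  if (!identical(dim(object@saturated), d))
    msg <- c(msg, "saturated mask must match values dimensions")
  if (object@frameOffset < 0) msg <- c(msg, "frameOffset must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Row-shift model
#'
#' Linear model of the wavelength shear in the raw stack: the filter sweeps
#' at constant speed and has a linear gradient, so the frame at which a
#' given wavelength reaches row `y` grows linearly in `y`. `slope` is in
#' frames per row; de-shearing row `y` of output frame `f'` reads source
#' frame `f' - slope * (y - referenceRow)`.
#'
#' @slot slope frames per row.
#' @slot referenceRow 1-based row index at which the shift is zero.
#' @seealso [estimateRowShift()], [fitShiftModel()], [deshearStack()]
#' @export
setClass("ShiftModel",
  representation(slope = "numeric", referenceRow = "numeric")
)

setValidity("ShiftModel", function(object) {
  if (!is.finite(object@slope)) "slope must be finite" else TRUE
})

#' Frame-to-wavelength map
#'
#' Linear map `lambda = mLambda * frame + bLambda` anchored on the two
#' grey-plate onsets: the frame where the blue channel signal starts
#' (assigned 436 nm) and the frame where the red channel signal ends
#' (assigned 642 nm). Frame numbers are 0-based within the de-sheared
#' stack.
#'
#' @slot mLambda slope in nm per frame (must be positive).
#' @slot bLambda intercept in nm.
#' @slot frameBlueOnset,frameRedOnset anchor frame numbers.
#' @slot lambdaBlue,lambdaRed anchor wavelengths (436 and 642 nm).
#' @seealso [detectOnsets()], [buildWavelengthMap()],
#'   [framesToWavelength()]
#' @export
setClass("WavelengthMap",
  representation(
    mLambda = "numeric", bLambda = "numeric",
    frameBlueOnset = "numeric", frameRedOnset = "numeric",
    lambdaBlue = "numeric", lambdaRed = "numeric"
  )
)

setValidity("WavelengthMap", function(object) {
  msg <- character()
  if (object@mLambda <= 0) msg <- c(msg, "mLambda must be > 0")
  for (a in c("Blue", "Red")) {
    fr <- slot(object, paste0("frame", a, "Onset"))
    lam <- slot(object, paste0("lambda", a))
    if (abs(object@mLambda * fr + object@bLambda - lam) > 1e-9)
      msg <- c(msg, sprintf("map must reproduce the %s anchor exactly", tolower(a)))
  }
  if (length(msg)) msg else TRUE
})

#' Reflectance hypercube
#'
#' The pipeline's product: a `(row, col, band)` array of reflectance values
#' on a strictly ascending wavelength grid, with a per-entry validity mask
#' (bands outside the scan's wavelength coverage, or saturated pixels, are
#' masked and excluded from statistics).
#'
#' @slot values double array `(row, col, band)`; reflectance, unitless.
#' @slot bandCenters strictly increasing band center wavelengths (nm).
#' @slot validMask logical array matching `values`.
#' @slot scene ground-truth [SceneSpec-class] or `NULL`.
#' @slot processing list of provenance entries (shift model, wavelength
#'   map, calibration settings) accumulated by the pipeline.
#' @seealso [buildCube()], [calibrateReflectance()], [writeENVI()]
#' @export
setClass("Hypercube",
  representation(
    values = "array", bandCenters = "numeric", validMask = "array",
    scene = "ANY", processing = "list"
  )
)

setValidity("Hypercube", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3) msg <- c(msg, "values must be a 3-D (row, col, band) array")
  else {
    if (length(object@bandCenters) != d[3])
      msg <- c(msg, "bandCenters length must equal the band dimension")
    if (!identical(dim(object@validMask), d))
      msg <- c(msg, "validMask must match values dimensions")
  }
  if (length(object@bandCenters) > 1 &&
      is.unsorted(object@bandCenters, strictly = TRUE))
    msg <- c(msg, "bandCenters must be strictly increasing")
  v <- object@values[object@validMask]
  if (length(v) && min(v) < -1e-9)
    msg <- c(msg, "valid reflectance values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Labeled per-pixel spectral library
#'
#' Flat table of annotated pixels: one 45-band (by default) reflectance
#' vector per pixel together with its cube of origin, position and class
#' label. Feeds [trainModel()].
#'
#' @slot spectra numeric matrix, one row per pixel, one column per band.
#' @slot info data.frame with columns `cubeId`, `row`, `col`, `class`
#'   (1-based pixel coordinates).
#' @slot bandCenters band center wavelengths (nm) of the columns.
#' @seealso [extractLabeledPixels()], [classMeanSpectra()],
#'   [splitTrainVal()]
#' @export
setClass("SpectralLibrary",
  representation(spectra = "matrix", info = "data.frame",
                 bandCenters = "numeric")
)

setValidity("SpectralLibrary", function(object) {
  msg <- character()
  if (nrow(object@spectra) != nrow(object@info))
    msg <- c(msg, "spectra and info must have the same number of rows")
  if (ncol(object@spectra) != length(object@bandCenters))
    msg <- c(msg, "spectra columns must match bandCenters")
  need <- c("cubeId", "row", "col", "class")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, "info must have columns cubeId, row, col, class")
  else {
    key <- paste(object@info$cubeId, object@info$row, object@info$col)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (cubeId, row, col) records are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' One-dimensional convolutional network for per-pixel spectra
#'
#' Compact 1D-CNN classifying single-pixel reflectance vectors:
#' conv(32, k3, s1, p1) - ReLU - maxpool(2) - dropout(0.25) -
#' conv(64, k3, s1, p1) - ReLU - maxpool(2) - dropout(0.25) - flatten -
#' dense(128) - ReLU - dense(128) - ReLU - linear(nClasses), trained with
#' cross-entropy and Adam. Weights live in `params`; `history` records
#' per-epoch training/validation loss.
#'
#' @slot nBands input spectrum length (default 45).
#' @slot nClasses number of output classes (default 5: four species plus
#'   background).
#' @slot classLabels class names in output-unit order.
#' @slot hyper list of architecture hyperparameters (`conv1Filters`,
#'   `conv2Filters`, `kernel`, `pool`, `dropout`, `denseUnits`).
#' @slot params named list of weight/bias arrays.
#' @slot trained logical.
#' @slot history data.frame (`epoch`, `trainLoss`, `valLoss`).
#' @seealso [buildModel()], [trainModel()], [predictCube()]
#' @export
setClass("ConvNet1D",
  representation(
    nBands = "integer", nClasses = "integer", classLabels = "character",
    hyper = "list", params = "list", trained = "logical",
    history = "data.frame"
  )
)

setValidity("ConvNet1D", function(object) {
  msg <- character()
  if (object@nBands < 4)
    msg <- c(msg, "nBands must be >= 4 (two pooling layers halve it twice)")
  if (object@nClasses < 2) msg <- c(msg, "nClasses must be >= 2")
  if (length(object@classLabels) != object@nClasses)
    msg <- c(msg, "classLabels must have nClasses entries")
  h <- object@hyper
  need <- c("conv1Filters", "conv2Filters", "kernel", "pool", "dropout",
            "denseUnits")
  if (!all(need %in% names(h)))
    msg <- c(msg, "hyper must contain conv1Filters, conv2Filters, kernel, pool, dropout, denseUnits")
  else if (any(unlist(h[c("conv1Filters", "conv2Filters", "kernel", "pool",
                          "denseUnits")]) <= 0))
    msg <- c(msg, "architecture hyperparameters must be positive")
  if (length(msg)) msg else TRUE
})

#' Segmentation metrics
#'
#' Per-class precision, recall and F1 over annotated pixels, plus macro
#' averages across the foreground (species) classes, mirroring how
#' segmentation of the four macroalgae is scored (background participates
#' in training but not in the macro average).
#'
#' @slot perClass data.frame with columns `class`, `precision`, `recall`,
#'   `f1`, `support` (`NA` where a class is absent from the ground truth).
#' @slot macro named numeric vector (`precision`, `recall`, `f1`).
#' @seealso [evaluateSegmentation()]
#' @export
setClass("ClassMetrics",
  representation(perClass = "data.frame", macro = "numeric")
)

setValidity("ClassMetrics", function(object) {
  need <- c("class", "precision", "recall", "f1", "support")
  ok <- all(need %in% names(object@perClass)) &&
    all(c("precision", "recall", "f1") %in% names(object@macro))
  vals <- unlist(object@perClass[c("precision", "recall", "f1")])
  vals <- vals[!is.na(vals)]
  if (!ok) return("perClass/macro are missing required fields")
  if (length(vals) && (min(vals) < 0 || max(vals) > 1))
    return("metrics must lie in [0, 1]")
  TRUE
})
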
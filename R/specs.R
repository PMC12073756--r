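# User-facing constructors and show() methods for the spec classes.

#' @include AllClasses.R AllGenerics.R
NULL

#' Create a filter specification
#'
#' Defaults describe the 47.8 mm linearly variable bandpass filter used by
#' the instrument: center wavelength graded linearly from 400 to 700 nm and
#' FWHM from 3 to 9 nm along its length.
#'
#' @param lengthMM filter length in mm.
#' @param cwlStart,cwlEnd center wavelength (nm) at the filter ends.
#' @param fwhmStart,fwhmEnd FWHM (nm) at the filter ends.
#' @param peakTransmittance peak transmittance in `[0, 1]`.
#' @return A [FilterSpec-class] object.
#' @examples
#' f <- FilterSpec()
#' filterTransmission(f, 0.5, 550)  # peak at the midpoint CWL
#' @export
FilterSpec <- function(lengthMM = 47.8, cwlStart = 400, cwlEnd = 700,
                       fwhmStart = 3, fwhmEnd = 9, peakTransmittance = 1.0) {
  new("FilterSpec", lengthMM = lengthMM, cwlStart = cwlStart,
      cwlEnd = cwlEnd, fwhmStart = fwhmStart, fwhmEnd = fwhmEnd,
      peakTransmittance = peakTransmittance)
}

#' Default camera gamma curves
#'
#' Power-law video-style encoding `count = round(255 * power^exponent)` with
#' hard saturation at 255, sampled at `nKnots` power levels per channel.
#' `exponent = 1` yields an identity (linear) sensor.
#'
#' @param exponent encoding exponent (default 0.45).
#' @param nKnots number of knots sampled on `[0, 1]`.
#' @return Named list of three [GammaCurve-class] objects (`R`, `G`, `B`).
#' @export
defaultGammaCurves <- function(exponent = 0.45, nKnots = 21) {
  p <- seq(0, 1, length.out = nKnots)
  cnt <- round(255 * p^exponent)
  stats::setNames(lapply(.CHANNELS, function(ch) {
    new("GammaCurve", channel = ch, knots = cbind(power = p, count = cnt))
  }), .CHANNELS)
}

#' Create a camera specification
#'
#' Defaults model the simulated sensor: 240 Hz, 8-bit, 128 x 160 pixels,
#' power-law gamma encoding (exponent 0.45) and Gaussian channel
#' sensitivities centered at 600/540/460 nm. The sensitivity widths are set
#' so that, on the neutral grey plate, the blue channel's 10 %-of-maximum
#' rise sits at 436 nm and the red channel's fall at 642 nm -- the two
#' wavelength anchors the reconstruction uses.
#'
#' @param frameRate frames per second.
#' @param bitDepth bits per channel.
#' @param rows,cols sensor dimensions.
#' @param gamma named list of three [GammaCurve-class] objects.
#' @param sensMean,sensSd named numeric vectors (`R`, `G`, `B`): Gaussian
#'   sensitivity centers and widths in nm.
#' @param gain linear signal gain; `NA` emulates auto-exposure (the
#'   scene's brightest signal is scaled to 0.95, just below saturation).
#' @return A [CameraSpec-class] object.
#' @export
CameraSpec <- function(frameRate = 240, bitDepth = 8, rows = 128, cols = 160,
                       gamma = defaultGammaCurves(),
                       sensMean = c(R = 600, G = 540, B = 460),
                       sensSd = c(R = 18.8, G = 30, B = 11.4),
                       gain = NA_real_) {
  new("CameraSpec", frameRate = frameRate, bitDepth = bitDepth,
      rows = as.integer(rows), cols = as.integer(cols), gamma = gamma,
      sensMean = sensMean[.CHANNELS], sensSd = sensSd[.CHANNELS],
      gain = gain)
}

#' Create a scan specification
#'
#' @param nFrames frames per full filter sweep (70-350 practical range).
#' @param shiftSlope true row shift in frames per row.
#' @param noiseSd additive Gaussian noise (linear intensity units).
#' @param seed integer RNG seed.
#' @return A [ScanSpec-class] object.
#' @export
ScanSpec <- function(nFrames = 240, shiftSlope = 0.2, noiseSd = 0.005,
                     seed = 1L) {
  new("ScanSpec", nFrames = as.integer(nFrames), shiftSlope = shiftSlope,
      noiseSd = noiseSd, seed = as.integer(seed))
}

setMethod("show", "FilterSpec", function(object) {
  cat(sprintf(
    "FilterSpec: %.1f mm, CWL %g-%g nm, FWHM %g-%g nm, peak T = %g\n",
    object@lengthMM, object@cwlStart, object@cwlEnd,
    object@fwhmStart, object@fwhmEnd, object@peakTransmittance))
})

setMethod("show", "CameraSpec", function(object) {
  cat(sprintf(
    "CameraSpec: %d x %d px, %g fps, %d-bit, gain %s\n",
    object@rows, object@cols, object@frameRate, as.integer(object@bitDepth),
    if (is.na(object@gain)) "auto" else format(object@gain)))
})

setMethod("show", "ScanSpec", function(object) {
  cat(sprintf(
    "ScanSpec: %d frames, shift %.3f frames/row, noise sd %g, seed %d\n",
    object@nFrames, object@shiftSlope, object@noiseSd, object@seed))
})

setMethod("show", "SceneSpec", function(object) {
  tab <- table(factor(object@labelMap, levels = 0:length(object@classNames),
                      labels = c("grey", object@classNames)))
  cat(sprintf("SceneSpec: %d x %d px, grey R = %g, margin %d rows\n",
              nrow(object@labelMap), ncol(object@labelMap),
              object@greyReflectance, object@marginRows))
  cat("  pixels per class:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "RawScanStack", function(object) {
  d <- dim(object@counts)
  cat(sprintf(
    "RawScanStack: %d frames x %d x %d px x 3 channels (%d-bit), count range [%d, %d]\n",
    d[1], d[2], d[3], as.integer(object@camera@bitDepth),
    min(object@counts), max(object@counts)))
})

setMethod("show", "LinearScan", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "LinearScan: %d frames x %d x %d px x 3 channels, %s, %.2f%% saturated\n",
    d[1], d[2], d[3],
    if (object@desheared) sprintf("de-sheared (frame offset %d)", object@frameOffset)
    else "sheared",
    100 * mean(object@saturated)))
})

setMethod("show", "ShiftModel", function(object) {
  cat(sprintf("ShiftModel: %.4f frames/row (reference row %g)\n",
              object@slope, object@referenceRow))
})

setMethod("show", "WavelengthMap", function(object) {
  cat(sprintf(
    "WavelengthMap: lambda = %.4f * frame + %.2f nm  (anchors: frame %g -> %g nm, frame %g -> %g nm)\n",
    object@mLambda, object@bLambda,
    object@frameBlueOnset, object@lambdaBlue,
    object@frameRedOnset, object@lambdaRed))
})

setMethod("show", "Hypercube", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "Hypercube: %d x %d px x %d bands (%.1f-%.1f nm), %.1f%% valid\n",
    d[1], d[2], d[3], min(object@bandCenters), max(object@bandCenters),
    100 * mean(object@validMask)))
})

setMethod("show", "SpectralLibrary", function(object) {
  tab <- table(object@info$class)
  cat(sprintf("SpectralLibrary: %d pixels x %d bands\n",
              nrow(object@spectra), ncol(object@spectra)))
  cat("  records per class:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ConvNet1D", function(object) {
  h <- object@hyper
  cat(sprintf(
    "ConvNet1D: %d bands -> conv(%d,k%d) -> pool -> conv(%d,k%d) -> pool -> flatten(%d) -> dense(%d) -> dense(%d) -> %d classes [%s]\n",
    object@nBands, h$conv1Filters, h$kernel, h$conv2Filters, h$kernel,
    flattenLength(object@nBands, h$conv2Filters, h$pool),
    h$denseUnits, h$denseUnits, object@nClasses,
    if (object@trained) "trained" else "untrained"))
})

setMethod("show", "ClassMetrics", function(object) {
  cat("ClassMetrics (per annotated pixel):\n")
  df <- object@perClass
  df[c("precision", "recall", "f1")] <-
    lapply(df[c("precision", "recall", "f1")], round, 4)
  print(df, row.names = FALSE)
  cat(sprintf("Macro (species classes): precision %.4f, recall %.4f, F1 %.4f\n",
              object@macro["precision"], object@macro["recall"],
              object@macro["f1"]))
})

#' @rdname accessors
setMethod("counts", "RawScanStack", function(x) x@counts)

#' @rdname accessors
setMethod("cubeValues", "Hypercube", function(x) x@values)

#' @rdname accessors
setMethod("bandCenters", "Hypercube", function(x) x@bandCenters)

#' @rdname accessors
setMethod("bandCenters", "SpectralLibrary", function(x) x@bandCenters)

#' @rdname accessors
setMethod("validMask", "Hypercube", function(x) x@validMask)

#' @rdname accessors
setMethod("nBands", "Hypercube", function(x) length(x@bandCenters))

#' @rdname accessors
setMethod("nBands", "SpectralLibrary", function(x) ncol(x@spectra))

#' @rdname accessors
setMethod("nBands", "ConvNet1D", function(x) x@nBands)

#' @rdname accessors
setMethod("classLabels", "SpectralLibrary",
          function(x) sort(unique(x@info$class)))

#' @rdname accessors
setMethod("classLabels", "ConvNet1D", function(x) x@classLabels)

#' @rdname accessors
setMethod("shiftSlope", "ShiftModel", function(x) x@slope)

#' Spectra and pixel metadata of a spectral library
#'
#' @param x a [SpectralLibrary-class].
#' @return `librarySpectra()` the pixel-by-band matrix; `libraryInfo()` the
#'   matching metadata data.frame.
#' @export
librarySpectra <- function(x) {
  stopifnot(is(x, "SpectralLibrary"))
  x@spectra
}

#' @rdname librarySpectra
#' @export
libraryInfo <- function(x) {
  stopifnot(is(x, "SpectralLibrary"))
  x@info
}
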
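# Forward model of the scanning-filter camera: filter transmission,
# reference reflectance spectra, scene construction, and scan rendering.

#' @include AllClasses.R specs.R
NULL

# Run code with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Filter transmittance at a position and wavelength
#'
#' Evaluates the Gaussian passband of the linearly variable filter. The band
#' center and FWHM are linearly interpolated between the filter's two ends:
#' at fractional position `p` the center is
#' `cwlStart + p * (cwlEnd - cwlStart)` and the width
#' `fwhmStart + p * (fwhmEnd - fwhmStart)`.
#'
#' @param spec a [FilterSpec-class].
#' @param positionFrac fractional position along the filter in `[0, 1]`
#'   (0 = blue end).
#' @param wavelength wavelength in nm, within `[350, 750]`.
#' @return Transmittance in `[0, peakTransmittance]`; vectorized over both
#'   arguments (recycled).
#' @examples
#' filterTransmission(FilterSpec(), 0.5, 550)   # band center: peak
#' filterTransmission(FilterSpec(), 1.0, 704.5) # half maximum at +FWHM/2
#' @export
filterTransmission <- function(spec, positionFrac, wavelength) {
  stopifnot(is(spec, "FilterSpec"))
  if (any(positionFrac < 0 | positionFrac > 1))
    stop("positionFrac must lie in [0, 1]")
  if (any(wavelength < 350 | wavelength > 750))
    stop("wavelength must lie in [350, 750] nm")
  cwl <- spec@cwlStart + positionFrac * (spec@cwlEnd - spec@cwlStart)
  fwhm <- spec@fwhmStart + positionFrac * (spec@fwhmEnd - spec@fwhmStart)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  spec@peakTransmittance * exp(-(wavelength - cwl)^2 / (2 * sigma^2))
}

# Dip-parameterized smooth reflectance: rising cubic baseline minus Gaussian
# absorption dips. Dip centers are pre-shifted so the *observed* local minima
# sit at the nominal pigment wavelengths despite the sloped baseline.
.spectrumDips <- list(
  brown_a = list(base = 0.06, slope = 0.16,
                 center = c(445.10, 496.67, 607.44, 643.69),
                 depth  = c(0.045, 0.020, 0.015, 0.040),
                 width  = c(11, 9, 9, 10)),
  brown_b = list(base = 0.06, slope = 0.13,
                 center = c(445.08, 496.54, 606.43, 643.16),
                 depth  = c(0.045, 0.020, 0.015, 0.040),
                 width  = c(11, 9, 9, 10)),
  red_a   = list(base = 0.09, slope = 0.22,
                 center = c(440.09, 491.83, 606.49, 642.31),
                 depth  = c(0.050, 0.020, 0.025, 0.045),
                 width  = c(11, 9, 9, 10)),
  red_b   = list(base = 0.07, slope = 0.18,
                 center = c(440.08, 481.60, 602.90, 641.63),
                 depth  = c(0.050, 0.020, 0.015, 0.045),
                 width  = c(11, 9, 9, 10))
)

#' Reference reflectance spectra of the simulated classes
#'
#' Smooth synthetic reflectance spectra over 400-700 nm emulating the
#' optical fingerprints of the imaged macroalgae: chlorophyll-a absorption
#' produces reflectance minima near 445 and 641 nm for the brown classes and
#' 440 and 639 nm for the red classes, with lesser accessory-pigment dips
#' (496/603 nm brown; 491/603 and 481/598 nm for the two red classes). Red
#' classes have higher reflectance in the red region, every class peaks at
#' the long-wavelength end, and `"grey"` is the flat R = 0.1 background
#' plate. Outside 400-700 nm the spectra continue at their boundary value.
#'
#' @param className one of `"brown_a"`, `"brown_b"`, `"red_a"`, `"red_b"`,
#'   `"grey"`.
#' @param greyReflectance flat reflectance returned for `"grey"`.
#' @return A function of wavelength (nm) returning reflectance in `[0, 1]`.
#' @examples
#' lam <- seq(430, 470, by = 0.5)
#' f <- referenceSpectrum("brown_a")
#' lam[which.min(f(lam))]  # 445 nm
#' @export
referenceSpectrum <- function(className, greyReflectance = 0.1) {
  if (identical(className, "grey")) {
    force(greyReflectance)
    return(function(lambda) rep(greyReflectance, length(lambda)))
  }
  if (!className %in% names(.spectrumDips))
    stop("unknown class '", className, "'; available: ",
         paste(c(names(.spectrumDips), "grey"), collapse = ", "))
  p <- .spectrumDips[[className]]
  function(lambda) {
    l <- pmin(pmax(lambda, 400), 700)
    r <- p$base + p$slope * ((l - 400) / 300)^3
    for (i in seq_along(p$center))
      r <- r - p$depth[i] * exp(-(l - p$center[i])^2 / (2 * p$width[i]^2))
    pmin(pmax(r, 0), 1)
  }
}

# Rectangle helper: set labelMap[rows, cols] <- label.
.fillRect <- function(labelMap, rows, cols, label) {
  labelMap[rows, cols] <- label
  labelMap
}

#' Construct a synthetic scene
#'
#' Builds a [SceneSpec-class] on the sensor grid with a neutral grey plate
#' background (flat R = 0.1) and rectangular class patches. Grey margin rows
#' are always kept at the top and bottom of the frame; the pipeline relies
#' on them for row-shift estimation and onset detection. Layouts:
#'
#' * `"four_species"`: four equal patches (2 x 2 grid) carrying the four
#'   [referenceSpectrum()] classes; the patch-to-quadrant assignment is a
#'   seeded permutation.
#' * `"flat_patch"`: one centered patch with a flat reflectance `flatR`.
#'
#' Alternatively, pass an integer `labelMap` matrix (0 = grey) with matching
#' `classes`.
#'
#' @param layout preset name or an integer label matrix.
#' @param classes named list of reflectance functions for labels `1..K`
#'   (defaults to the four reference spectra for `"four_species"`).
#' @param rows,cols scene dimensions in pixels.
#' @param marginRows guaranteed grey rows at the top and bottom.
#' @param flatR flat reflectance of the `"flat_patch"` layout.
#' @param greyReflectance background plate reflectance.
#' @param illumination spectral radiance function (relative units).
#' @param seed integer seed controlling the layout permutation.
#' @return A [SceneSpec-class].
#' @examples
#' sc <- makeScene("four_species", seed = 1)
#' table(sc@labelMap)
#' @export
makeScene <- function(layout = "four_species", classes = NULL,
                      rows = 128, cols = 160, marginRows = 12, flatR = 0.5,
                      greyReflectance = 0.1,
                      illumination = function(lambda) rep(1, length(lambda)),
                      seed = 1L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  marginRows <- as.integer(marginRows)
  if (is.matrix(layout)) {
    labelMap <- matrix(as.integer(layout), nrow(layout), ncol(layout))
    if (is.null(classes)) stop("a custom labelMap requires 'classes'")
    classNames <- names(classes)
  } else if (identical(layout, "four_species")) {
    classNames <- c("brown_a", "brown_b", "red_a", "red_b")
    if (is.null(classes))
      classes <- stats::setNames(lapply(classNames, referenceSpectrum),
                                 classNames)
    labelMap <- matrix(0L, rows, cols)
    gap <- max(4L, as.integer(round(0.06 * rows)))
    rIn <- c(marginRows + 1L, rows - marginRows)
    cm <- max(4L, as.integer(round(0.05 * cols)))
    cIn <- c(cm + 1L, cols - cm)
    rh <- (rIn[2] - rIn[1] + 1L - gap) %/% 2L
    cw <- (cIn[2] - cIn[1] + 1L - gap) %/% 2L
    if (rh < 4 || cw < 4) stop("scene too small for the four_species layout")
    rBlocks <- list(rIn[1] + 0:(rh - 1L), rIn[2] - (rh - 1L):0)
    cBlocks <- list(cIn[1] + 0:(cw - 1L), cIn[2] - (cw - 1L):0)
    perm <- .withSeed(seed, sample.int(4L))
    q <- 0L
    for (ri in 1:2) for (ci in 1:2) {
      q <- q + 1L
      labelMap <- .fillRect(labelMap, rBlocks[[ri]], cBlocks[[ci]], perm[q])
    }
  } else if (identical(layout, "flat_patch")) {
    classNames <- "flat"
    fr <- force(flatR)
    classes <- list(flat = function(lambda) rep(fr, length(lambda)))
    labelMap <- matrix(0L, rows, cols)
    rh <- as.integer(round(rows * 0.25)); cw <- as.integer(round(cols * 0.3))
    rc <- rows %/% 2L; cc <- cols %/% 2L
    labelMap <- .fillRect(labelMap, (rc - rh):(rc + rh), (cc - cw):(cc + cw),
                          1L)
  } else stop("unknown layout preset '", layout, "'")
  spectra <- c(list(grey = referenceSpectrum("grey", greyReflectance)),
               classes)
  new("SceneSpec", labelMap = labelMap, classNames = classNames,
      spectra = spectra, illumination = illumination,
      greyReflectance = greyReflectance, marginRows = marginRows)
}

# Per-channel Gaussian spectral sensitivities evaluated on a wavelength grid.
.channelSensitivity <- function(camera, lambda) {
  vapply(.CHANNELS, function(ch) {
    exp(-(lambda - camera@sensMean[ch])^2 / (2 * camera@sensSd[ch]^2))
  }, numeric(length(lambda)))
}

# Spectral signal integrals per (filter position, class, channel).
# Returns list(pGrid, E) with E an array [nP, nClass, 3].
.signalTable <- function(scene, camera, filter, nP = 2048L) {
  lam <- seq(390, 710, by = 1)
  L <- scene@illumination(lam)
  if (any(L < 0)) stop("illumination must be non-negative")
  S <- .channelSensitivity(camera, lam)
  classSeq <- c("grey", scene@classNames)
  Rk <- vapply(classSeq, function(nm) scene@spectra[[nm]](lam),
               numeric(length(lam)))
  pGrid <- seq(0, 1, length.out = nP)
  cwl <- filter@cwlStart + pGrid * (filter@cwlEnd - filter@cwlStart)
  fwhm <- filter@fwhmStart + pGrid * (filter@fwhmEnd - filter@fwhmStart)
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  # transmission matrix [nP, nLambda]
  TR <- filter@peakTransmittance *
    exp(-sweep(matrix(lam, nP, length(lam), byrow = TRUE), 1, cwl)^2 /
          (2 * sig^2))
  W <- matrix(0, length(lam), length(classSeq) * 3L)
  for (k in seq_along(classSeq)) for (c in 1:3)
    W[, (k - 1L) * 3L + c] <- L * Rk[, k] * S[, c]
  E <- TR %*% W  # 1-nm quadrature
  dim(E) <- c(nP, 3L, length(classSeq))
  E <- aperm(E, c(1, 3, 2))
  list(pGrid = pGrid, E = E, classSeq = classSeq, sceneMax = max(E))
}

#' Render a raw scan of a scene
#'
#' Forward-simulates the instrument: for frame `f` and row `y` (0-based) the
#' filter's effective fractional position is
#' `(f + shiftSlope * y) / nFrames`, clipped to `[0, 1]` -- the moving
#' filter makes every row of every frame observe a different passband. The
#' linear pixel signal is the 1-nm quadrature of
#' illumination x reflectance x filter transmission x channel sensitivity,
#' scaled by the camera gain, plus additive Gaussian noise, then passed
#' through the forward gamma curve and quantized to the camera bit depth.
#' Deterministic for a fixed `scan@seed`.
#'
#' @param scene a [SceneSpec-class] whose `labelMap` matches the camera
#'   geometry.
#' @param camera a [CameraSpec-class].
#' @param filter a [FilterSpec-class].
#' @param scan a [ScanSpec-class].
#' @param output `"counts"` for the quantized [RawScanStack-class] (default)
#'   or `"linear"` for the pre-gamma, pre-quantization linear intensity
#'   array (noise included; used by round-trip oracles).
#' @return A [RawScanStack-class], or a double array for
#'   `output = "linear"`.
#' @examples
#' sc <- makeScene("flat_patch", rows = 32, cols = 24, marginRows = 6)
#' cam <- CameraSpec(rows = 32, cols = 24)
#' stk <- renderScan(sc, cam, FilterSpec(), ScanSpec(nFrames = 80, seed = 3))
#' @export
renderScan <- function(scene, camera, filter = FilterSpec(),
                       scan = ScanSpec(), output = c("counts", "linear")) {
  output <- match.arg(output)
  stopifnot(is(scene, "SceneSpec"), is(camera, "CameraSpec"),
            is(filter, "FilterSpec"), is(scan, "ScanSpec"))
  if (nrow(scene@labelMap) != camera@rows ||
      ncol(scene@labelMap) != camera@cols)
    stop("scene labelMap dimensions must match the camera rows/cols")
  tab <- .signalTable(scene, camera, filter)
  # auto-exposure: the brightest signal any scene class produces maps to
  # 0.95, just below saturation
  gain <- if (is.na(camera@gain)) 0.95 / tab$sceneMax else camera@gain
  nF <- scan@nFrames; nR <- camera@rows; nC <- camera@cols
  nK <- length(tab$classSeq)
  lab1 <- scene@labelMap + 1L  # 1-based class index into classSeq
  rowIdx <- rep.int(seq_len(nR), nC)
  lin <- array(0, dim = c(nF, nR, nC, 3L))
  y0 <- 0:(nR - 1L)
  .withSeed(scan@seed, {
    for (f in seq_len(nF)) {
      p <- pmin(pmax((f - 1 + scan@shiftSlope * y0) / nF, 0), 1)
      # per-row signal for every class/channel at this frame's positions
      Ef <- array(0, dim = c(nR, nK, 3L))
      for (k in seq_len(nK)) for (c in 1:3)
        Ef[, k, c] <- stats::approx(tab$pGrid, tab$E[, k, c], xout = p)$y
      for (c in 1:3) {
        v <- matrix(Ef[cbind(rowIdx, as.vector(lab1), c)], nR, nC)
        lin[f, , , c] <- gain * v
      }
      if (scan@noiseSd > 0)
        lin[f, , , ] <- lin[f, , , ] +
          stats::rnorm(nR * nC * 3L, sd = scan@noiseSd)
    }
  })
  lin[lin < 0] <- 0
  if (output == "linear") return(lin)
  mx <- as.integer(2^camera@bitDepth - 1)
  cnt <- array(0L, dim = dim(lin))
  for (c in 1:3) {
    fwd <- .gammaForwardFun(camera@gamma[[.CHANNELS[c]]])
    x <- pmin(lin[, , , c], 1)
    cnt[, , , c] <- pmin(pmax(as.integer(round(fwd(x))), 0L), mx)
  }
  new("RawScanStack", counts = cnt, camera = camera, scan = scan,
      scene = scene)
}
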
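# Reflectance calibration against the grey plate, Savitzky-Golay denoising
# along the band axis, and spectral binning.

#' @include AllClasses.R specs.R wavelength.R
NULL

#' Calibrate a hypercube to reflectance
#'
#' Divides every pixel's intensity spectrum by the mean grey-plate intensity
#' per band and scales by the plate's known flat reflectance:
#' `R(x, y, b) = rRef * I(x, y, b) / mean(I_grey(b))`. This removes the
#' illumination spectrum, the filter transmission, the channel
#' sensitivities and the medium in one step, because every pixel in a band
#' shares them with the grey reference. The grey-region mean reflectance
#' equals `rRef` per band by construction. Bands whose grey mean is zero
#' (or with no valid grey pixel) are masked invalid.
#'
#' @param cube an intensity [Hypercube-class] from [interpolateBands()].
#' @param greyRegion grey-plate pixels: `NULL` (use the scene's grey
#'   pixels), a logical (row x col) mask, or
#'   `c(rowMin, rowMax, colMin, colMax)` (1-based, inclusive).
#' @param rRef the plate's flat reflectance (default 0.1).
#' @return A reflectance [Hypercube-class].
#' @export
calibrateReflectance <- function(cube, greyRegion = NULL, rRef = 0.1) {
  stopifnot(is(cube, "Hypercube"))
  d <- dim(cube@values)
  mask <- .resolveGreyRegion(greyRegion, cube@scene, d[1:2])
  if (!any(mask)) stop("grey region is empty")
  sel <- which(mask)
  npix <- d[1] * d[2]
  vals <- array(0, dim = d)
  valid <- cube@validMask
  greyMean <- numeric(d[3])
  V <- matrix(cube@values, npix, d[3])
  M <- matrix(cube@validMask, npix, d[3])
  gv <- V[sel, , drop = FALSE]
  gm <- M[sel, , drop = FALSE]
  gv[!gm] <- NA
  greyMean <- colMeans(gv, na.rm = TRUE)
  bad <- !is.finite(greyMean) | greyMean <= 0
  out <- sweep(V, 2, ifelse(bad, 1, greyMean), "/") * rRef
  out[, bad] <- 0
  valid <- M
  valid[, bad] <- FALSE
  new("Hypercube", values = array(out, d), bandCenters = cube@bandCenters,
      validMask = array(valid, d), scene = cube@scene,
      processing = c(cube@processing,
                     list(calibration = list(rRef = rRef,
                                             greyMean = greyMean))))
}

# Full Savitzky-Golay smoothing operator as a bands x bands matrix, built
# from the signal::sgolay coefficient matrix (interior rows slide the
# central filter; the first/last half-windows use the one-sided rows).
.sgolayMatrix <- function(nBands, order, window) {
  FF <- unclass(signal::sgolay(p = order, n = window))
  k <- (window - 1L) %/% 2L
  S <- matrix(0, nBands, nBands)
  for (i in seq_len(k)) S[i, seq_len(window)] <- FF[i, ]
  for (i in (k + 1L):(nBands - k)) S[i, (i - k):(i + k)] <- FF[k + 1L, ]
  for (i in seq_len(k))
    S[nBands - k + i, (nBands - window + 1L):nBands] <- FF[k + 1L + i, ]
  S
}

#' Savitzky-Golay denoising along the spectral axis
#'
#' Applies polynomial smoothing (default order 2, window 9) to every
#' pixel's spectrum; spatial dimensions are untouched. The filter
#' reproduces polynomials up to its order exactly, so constant and
#' quadratic spectra pass through unchanged.
#'
#' @param cube a [Hypercube-class].
#' @param order polynomial order.
#' @param window window length (odd, > order).
#' @return The smoothed [Hypercube-class].
#' @export
savgolDenoise <- function(cube, order = 2, window = 9) {
  stopifnot(is(cube, "Hypercube"))
  if (window %% 2 != 1 || window <= order)
    stop("window must be odd and greater than order")
  d <- dim(cube@values)
  # smooth only across the bands the scan actually covers: bands invalid
  # for every pixel hold no data and must not bleed into their neighbors
  gib <- .globallyInvalidBands(cube)
  idx <- which(!gib)
  if (length(idx) && all(diff(idx) == 1L)) {
    block <- idx
  } else {
    block <- seq_len(d[3])
  }
  if (length(block) < window)
    stop("cube has fewer covered bands (", length(block),
         ") than the filter window (", window, ")")
  S <- .sgolayMatrix(length(block), order, window)
  V <- matrix(cube@values, d[1] * d[2], d[3])
  out <- V
  out[, block] <- V[, block] %*% t(S)
  out[out < 0] <- 0
  new("Hypercube", values = array(out, d), bandCenters = cube@bandCenters,
      validMask = cube@validMask, scene = cube@scene,
      processing = c(cube@processing,
                     list(savgol = list(order = order, window = window))))
}

#' Bin wavelength channels
#'
#' Averages consecutive groups of `factor` bands (default 5), reducing
#' noise and data size; with the default 225-point grid this produces the
#' 45-band spectra the classifier consumes. Within each group, masked
#' entries are excluded from the average; a binned band is valid if at
#' least one member was. New band centers are the means of the member
#' centers.
#'
#' @param cube a [Hypercube-class] whose band count is divisible by
#'   `factor`.
#' @param factor binning factor.
#' @return The binned [Hypercube-class].
#' @export
binBands <- function(cube, factor = 5) {
  stopifnot(is(cube, "Hypercube"))
  factor <- as.integer(factor)
  if (factor == 1L) return(cube)
  d <- dim(cube@values)
  if (d[3] %% factor != 0)
    stop("band count (", d[3], ") is not divisible by factor ", factor,
         "; adjust the interpolation grid (see defaultBandGrid())")
  nB <- d[3] %/% factor
  grp <- rep(seq_len(nB), each = factor)
  V <- matrix(cube@values, d[1] * d[2], d[3])
  M <- matrix(cube@validMask, d[1] * d[2], d[3])
  Vm <- V * M
  # group sums via matrix product with the indicator of group membership
  G <- outer(seq_len(d[3]), seq_len(nB),
             function(i, g) as.numeric(grp[i] == g))
  sums <- Vm %*% G
  cnts <- M %*% G
  out <- sums / pmax(cnts, 1)
  out[cnts == 0] <- 0
  centers <- as.vector(tapply(cube@bandCenters, grp, mean))
  new("Hypercube", values = array(out, c(d[1], d[2], nB)),
      bandCenters = centers,
      validMask = array(cnts > 0, c(d[1], d[2], nB)),
      scene = cube@scene,
      processing = c(cube@processing, list(binning = list(factor = factor))))
}
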
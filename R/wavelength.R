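# Onset detection on the grey plate and the frame -> wavelength map.

#' @include AllClasses.R specs.R
NULL

# Mean grey-region trace per frame and channel of a de-sheared stack.
# Saturated entries are excluded from the mean.
.greyTrace <- function(scan, greyMask) {
  d <- dim(scan@values)
  sel <- which(greyMask)
  tr <- matrix(0, d[1], 3, dimnames = list(NULL, .CHANNELS))
  npix <- d[2] * d[3]
  for (c in 1:3) {
    v <- matrix(scan@values[, , , c], d[1], npix)[, sel, drop = FALSE]
    s <- matrix(scan@saturated[, , , c], d[1], npix)[, sel, drop = FALSE]
    v[s] <- NA
    tr[, c] <- rowMeans(v, na.rm = TRUE)
  }
  tr
}

# Resolve a grey-region specification into a logical (row, col) mask.
.resolveGreyRegion <- function(greyRegion, scene, dims) {
  if (is.null(greyRegion)) {
    if (is.null(scene))
      stop("greyRegion is required when no scene ground truth is attached")
    return(scene@labelMap == 0L)
  }
  if (is.matrix(greyRegion) && is.logical(greyRegion)) {
    if (!identical(dim(greyRegion), dims))
      stop("greyRegion mask dimensions must match the frame")
    return(greyRegion)
  }
  if (is.numeric(greyRegion) && length(greyRegion) == 4) {
    m <- matrix(FALSE, dims[1], dims[2])
    m[greyRegion[1]:greyRegion[2], greyRegion[3]:greyRegion[4]] <- TRUE
    return(m)
  }
  stop("greyRegion must be NULL, a logical mask, or c(rowMin, rowMax, colMin, colMax)")
}

#' Detect the blue and red onsets on the grey plate
#'
#' On a de-sheared stack, finds the frame where usable signal starts and
#' ends: the blue onset is the first frame whose blue-channel grey-region
#' mean rises above `threshold` times that channel's maximum, and the red
#' onset the last frame whose red-channel mean stays above the analogous
#' level. These two frames anchor the wavelength map at 436 and 642 nm.
#'
#' @param x a de-sheared [LinearScan-class], or a (frame x 3) trace matrix
#'   with columns `R`, `G`, `B`.
#' @param greyRegion grey-plate region (see [calibrateReflectance()] for
#'   accepted forms); defaults to the scene's grey pixels.
#' @param threshold fraction of the per-channel maximum (default 0.1).
#' @return Named numeric `c(blue = ..., red = ...)`: 0-based frame numbers.
#' @export
detectOnsets <- function(x, greyRegion = NULL, threshold = 0.1) {
  if (is(x, "LinearScan")) {
    if (!x@desheared)
      stop("onsets are detected on a de-sheared stack; run deshearStack() first")
    mask <- .resolveGreyRegion(greyRegion, x@scene, dim(x@values)[2:3])
    tr <- .greyTrace(x, mask)
  } else if (is.matrix(x) && ncol(x) == 3) {
    tr <- x
    if (is.null(colnames(tr))) colnames(tr) <- .CHANNELS
  } else stop("x must be a de-sheared LinearScan or a (frame x 3) trace matrix")
  pick <- function(channel, side) {
    t1 <- tr[, channel]
    mx <- max(t1)
    if (!is.finite(mx) || mx <= 0)
      stop("the ", channel, " channel trace never crosses the threshold")
    above <- which(t1 >= threshold * mx)
    if (!length(above))
      stop("the ", channel, " channel trace never crosses the threshold")
    if (side == "first") above[1] else above[length(above)]
  }
  c(blue = pick("B", "first") - 1, red = pick("R", "last") - 1)
}

#' Build the frame-to-wavelength map from onsets
#'
#' Anchors a linear map on the grey-plate onsets: the blue-onset frame is
#' assigned `lambdaBlue` (436 nm) and the red-onset frame `lambdaRed`
#' (642 nm), giving slope
#' `mLambda = (lambdaRed - lambdaBlue) / (frameRed - frameBlue)` and
#' intercept `bLambda = lambdaBlue - mLambda * frameBlue`.
#'
#' @param onsets named numeric `c(blue = ..., red = ...)` from
#'   [detectOnsets()], or the blue onset alone with `redOnset` supplied.
#' @param redOnset red onset frame when `onsets` is a scalar.
#' @param lambdaBlue,lambdaRed anchor wavelengths in nm.
#' @return A [WavelengthMap-class].
#' @examples
#' m <- buildWavelengthMap(c(blue = 100, red = 306))
#' framesToWavelength(m, 150)  # 486 nm
#' @export
buildWavelengthMap <- function(onsets, redOnset = NULL, lambdaBlue = 436,
                               lambdaRed = 642) {
  if (!is.null(redOnset)) onsets <- c(blue = unname(onsets[1]),
                                      red = redOnset)
  fb <- unname(onsets["blue"]); fr <- unname(onsets["red"])
  if (anyNA(c(fb, fr))) stop("onsets must be named c(blue = , red = )")
  if (fr == fb) stop("equal onsets: the wavelength map slope is undefined")
  if (fr < fb)
    stop("red onset precedes blue onset (negative dispersion): check the traces")
  m <- (lambdaRed - lambdaBlue) / (fr - fb)
  b <- lambdaBlue - m * fb
  new("WavelengthMap", mLambda = m, bLambda = b, frameBlueOnset = fb,
      frameRedOnset = fr, lambdaBlue = lambdaBlue, lambdaRed = lambdaRed)
}

#' Convert frame numbers to wavelengths
#'
#' Evaluates `lambda = mLambda * frame + bLambda`; exact at the two
#' anchors.
#'
#' @param map a [WavelengthMap-class].
#' @param frame 0-based frame number(s) in the de-sheared stack.
#' @return Wavelength(s) in nm.
#' @export
framesToWavelength <- function(map, frame) {
  stopifnot(is(map, "WavelengthMap"))
  map@mLambda * frame + map@bLambda
}

#' Default channel trim windows
#'
#' Wavelength windows (nm) outside which each RGB channel is zeroed before
#' summation, removing baseline noise where a channel carries no usable
#' signal: red 510-660, green 465-620, blue 430-566 nm.
#'
#' @return Named list of `c(min, max)` windows.
#' @export
channelTrimWindows <- function() {
  list(R = c(510, 660), G = c(465, 620), B = c(430, 566))
}
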
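# Row-shift estimation by cross-correlation of grey-plate traces, and
# de-shearing of the linearized stack into monochromatic frames.

#' @include AllClasses.R specs.R
NULL

# Normalized cross-correlation of two equal-length traces at integer lag k:
# cor(a[f], b[f - k]) over the overlapping frames.
.lagCorrelation <- function(a, b, lags) {
  n <- length(a)
  vapply(lags, function(k) {
    fa <- max(1, 1 + k):min(n, n + k)
    fb <- fa - k
    if (length(fa) < 8) return(NA_real_)
    sa <- stats::sd(a[fa]); sb <- stats::sd(b[fb])
    if (sa == 0 || sb == 0) return(NA_real_)
    stats::cor(a[fa], b[fb])
  }, numeric(1))
}

#' Estimate the row shift between two grey-plate pixels
#'
#' Cross-correlates the intensity-versus-frame traces of two pixels in the
#' same column (both on the grey plate) and returns the lag, in frames, by
#' which the deeper row's trace trails the shallower row's. The integer-lag
#' correlation peak is refined to sub-frame precision by parabolic
#' interpolation, computed per RGB channel and averaged.
#'
#' @param scan a sheared [LinearScan-class].
#' @param column column index (1-based).
#' @param rowTop,rowBottom row indices (1-based) of the two grey pixels.
#' @param maxLag largest candidate lag searched (default a third of the
#'   frame count).
#' @return Lag in frames (positive when the bottom row sees each wavelength
#'   earlier, i.e. for a positive scan shift slope).
#' @export
estimateRowShift <- function(scan, column, rowTop, rowBottom,
                             maxLag = NULL) {
  stopifnot(is(scan, "LinearScan"))
  nF <- dim(scan@values)[1]
  if (is.null(maxLag)) maxLag <- max(4L, nF %/% 3L)
  lags <- (-maxLag):maxLag
  perChannel <- vapply(1:3, function(c) {
    top <- scan@values[, rowTop, column, c]
    bot <- scan@values[, rowBottom, column, c]
    if (stats::sd(top) == 0 || stats::sd(bot) == 0)
      stop("flat (zero-variance) trace: rows must lie on the grey plate ",
           "and traces must be non-constant")
    r <- .lagCorrelation(top, bot, lags)
    i <- which.max(r)
    lag <- lags[i]
    # parabolic refinement of the correlation peak
    if (i > 1 && i < length(lags) && !anyNA(r[(i - 1):(i + 1)])) {
      den <- r[i - 1] - 2 * r[i] + r[i + 1]
      if (den < 0) lag <- lag + 0.5 * (r[i - 1] - r[i + 1]) / den
    }
    lag
  }, numeric(1))
  mean(perChannel)
}

#' Fit a linear shift model from row-pair lags
#'
#' The filter's linear gradient and constant sweep speed make the frame lag
#' proportional to the row separation; the slope (frames per row) is the
#' least-squares line through the (row separation, lag) pairs constrained
#' through the origin: `sum(dr * lag) / sum(dr^2)`.
#'
#' @param deltaRows row separations (rowBottom - rowTop).
#' @param lags matching lags in frames from [estimateRowShift()].
#' @param referenceRow row (1-based) at which the de-shear shift is zero.
#' @return A [ShiftModel-class].
#' @examples
#' fitShiftModel(100, 25)  # slope 0.25 frames/row
#' @export
fitShiftModel <- function(deltaRows, lags, referenceRow = 1) {
  if (length(deltaRows) < 1 || length(lags) != length(deltaRows))
    stop("need >= 1 (deltaRow, lag) pair")
  if (all(deltaRows == 0))
    stop("degenerate input: all row separations are zero")
  slope <- sum(deltaRows * lags) / sum(deltaRows^2)
  new("ShiftModel", slope = slope, referenceRow = referenceRow)
}

#' Estimate the shift model of a scan from its grey margins
#'
#' Convenience wrapper: runs [estimateRowShift()] on a top-margin and a
#' bottom-margin grey row at several columns and fits the shift model.
#'
#' @param scan a sheared [LinearScan-class] carrying a scene, or explicit
#'   `rowTop`/`rowBottom` on the grey plate.
#' @param columns column indices to use (default 5 evenly spaced).
#' @param rowTop,rowBottom grey rows (defaults: the middles of the scene's
#'   top and bottom margins).
#' @return A [ShiftModel-class] (reference row = `rowTop`).
#' @export
estimateShiftModel <- function(scan, columns = NULL, rowTop = NULL,
                               rowBottom = NULL) {
  stopifnot(is(scan, "LinearScan"))
  d <- dim(scan@values)
  if (is.null(rowTop) || is.null(rowBottom)) {
    if (is.null(scan@scene))
      stop("without scene ground truth, rowTop and rowBottom are required")
    m <- scan@scene@marginRows
    rowTop <- max(1L, m %/% 2L)
    rowBottom <- d[2] - rowTop + 1L
  }
  if (is.null(columns))
    columns <- unique(round(seq(d[3] * 0.1, d[3] * 0.9, length.out = 5)))
  lags <- vapply(columns, function(cl)
    estimateRowShift(scan, cl, rowTop, rowBottom), numeric(1))
  fitShiftModel(rep(rowBottom - rowTop, length(columns)), lags,
                referenceRow = rowTop)
}

#' De-shear a linearized stack into monochromatic frames
#'
#' Re-orders rows across frames so that every row of an output frame saw the
#' same filter position: output frame `f'`, row `y` takes source frame
#' `f' - slope * (y - referenceRow)`, rounded to the nearest frame. Output
#' frames for which any row would map outside the recorded range are
#' dropped; `frameOffset` records the 0-based source frame number of the
#' first kept frame.
#'
#' @param scan a sheared [LinearScan-class].
#' @param model a [ShiftModel-class].
#' @return A de-sheared [LinearScan-class].
#' @export
deshearStack <- function(scan, model) {
  stopifnot(is(scan, "LinearScan"), is(model, "ShiftModel"))
  if (scan@desheared)
    warning("stack is already de-sheared; applying the model again")
  d <- dim(scan@values)
  nF <- d[1]; nR <- d[2]
  off <- as.integer(round(model@slope * (seq_len(nR) - model@referenceRow)))
  start <- 1L + max(0L, max(off))
  end <- nF + min(0L, min(off))
  if (start > end)
    stop("shift slope too large: no frame has all rows in range")
  nV <- end - start + 1L
  vals <- array(0, dim = c(nV, nR, d[3], 3L))
  sat <- array(FALSE, dim = c(nV, nR, d[3], 3L))
  for (y in seq_len(nR)) {
    src <- (start:end) - off[y]
    vals[, y, , ] <- scan@values[src, y, , ]
    sat[, y, , ] <- scan@saturated[src, y, , ]
  }
  new("LinearScan", values = vals, saturated = sat, camera = scan@camera,
      scan = scan@scan, scene = scan@scene, desheared = TRUE,
      frameOffset = scan@frameOffset + start - 1L)
}
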
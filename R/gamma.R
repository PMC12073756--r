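# Gamma characterization and per-channel linearization of raw counts.

#' @include AllClasses.R specs.R
NULL

# Monotone forward spline count = F(power) through the curve's knots.
.gammaForwardFun <- function(curve) {
  k <- curve@knots
  if (nrow(k) == 2) {
    a <- (k[2, 2] - k[1, 2]) / (k[2, 1] - k[1, 1])
    function(p) k[1, 2] + a * (p - k[1, 1])
  } else {
    stats::splinefun(k[, 1], k[, 2], method = "hyman")
  }
}

# Dense inverse lookup: power = F^{-1}(count), plus the saturation count.
.gammaInverseFun <- function(curve, nGrid = 8192L) {
  fwd <- .gammaForwardFun(curve)
  pg <- seq(0, max(curve@knots[, 1]), length.out = nGrid)
  cv <- fwd(pg)
  satCount <- max(curve@knots[, 2])
  keep <- c(TRUE, diff(cv) > 1e-12)
  pk <- pg[keep]; ck <- cv[keep]
  satPower <- if (any(cv >= satCount - 1e-9))
    pg[which(cv >= satCount - 1e-9)[1]] else max(pg)
  list(
    invert = function(counts) {
      stats::approx(ck, pk, xout = pmin(counts, satCount), rule = 2)$y
    },
    satCount = satCount, satPower = satPower
  )
}

#' Evaluate a gamma curve (forward / inverse)
#'
#' `gammaForward()` maps normalized linear power in `[0, 1]` to (continuous)
#' digital counts through the curve's monotone spline; `gammaInverse()`
#' numerically inverts it, mapping counts back to linear power on the
#' curve's non-saturated range (counts at or above saturation return the
#' saturation power).
#'
#' @param curve a [GammaCurve-class].
#' @param power,counts numeric vectors.
#' @return Numeric vector of counts (forward) or powers (inverse).
#' @export
gammaForward <- function(curve, power) {
  stopifnot(is(curve, "GammaCurve"))
  if (any(power < 0 | power > 1)) stop("power must lie in [0, 1]")
  .gammaForwardFun(curve)(power)
}

#' @rdname gammaForward
#' @export
gammaInverse <- function(curve, counts) {
  stopifnot(is(curve, "GammaCurve"))
  .gammaInverseFun(curve)$invert(counts)
}

#' Fit a gamma curve from characterization measurements
#'
#' Fits the monotone camera response from empirical (normalized power,
#' digital count) pairs for one channel, as measured by imaging a target at
#' controlled attenuation levels. Counts are projected to a non-decreasing
#' sequence (isotonic regression; a warning reports any adjustment beyond
#' `tol` counts) and interpolated with a monotone Hyman spline, which is
#' invertible on its non-saturated range.
#'
#' @param power normalized linear powers in `[0, 1]` (>= 3 values).
#' @param count measured digital counts in `[0, 255]`.
#' @param channel one of `"R"`, `"G"`, `"B"`.
#' @param tol tolerated non-monotonicity (counts) before warning.
#' @return A [GammaCurve-class].
#' @examples
#' p <- seq(0, 1, by = 0.1)
#' fitGamma(p, round(255 * p), "G")  # linear sensor
#' @export
fitGamma <- function(power, count, channel = "R", tol = 0.5) {
  if (length(power) < 3 || length(count) != length(power))
    stop("need >= 3 (power, count) pairs per channel")
  if (any(power < 0 | power > 1)) stop("powers must lie in [0, 1]")
  o <- order(power)
  power <- power[o]; count <- count[o]
  # average duplicate powers
  if (anyDuplicated(power)) {
    count <- as.vector(tapply(count, power, mean))
    power <- sort(unique(power))
  }
  iso <- stats::isoreg(power, count)$yf
  if (max(abs(iso - count)) > tol)
    warning("non-monotone gamma measurements for channel ", channel,
            "; isotonic projection applied")
  if (power[1] != 0) {
    power <- c(0, power); iso <- c(0, iso)
  }
  iso[1] <- 0  # response is anchored at (0, 0)
  new("GammaCurve", channel = channel,
      knots = cbind(power = power, count = pmin(iso, 255)))
}

#' Fit gamma curves for all channels from a measurement table
#'
#' @param table data.frame with columns `channel`, `power`, `count` (the
#'   on-disk CSV format; see [readGammaTable()]).
#' @return Named list of [GammaCurve-class] objects.
#' @export
fitGammaCurves <- function(table) {
  need <- c("channel", "power", "count")
  if (!all(need %in% names(table)))
    stop("gamma table must have columns channel, power, count")
  chans <- intersect(.CHANNELS, unique(table$channel))
  if (!length(chans)) stop("gamma table contains no R/G/B measurements")
  stats::setNames(lapply(chans, function(ch) {
    sub <- table[table$channel == ch, ]
    fitGamma(sub$power, sub$count, ch)
  }), chans)
}

#' Synthesize a gamma characterization table from a camera
#'
#' Emulates the gamma measurement procedure on a simulated camera: the
#' forward curve of each channel is sampled at a ladder of attenuation
#' levels and quantized to integer counts, producing the same CSV table the
#' physical characterization yields.
#'
#' @param camera a [CameraSpec-class].
#' @param powers attenuation levels in `[0, 1]`.
#' @return data.frame with columns `channel`, `power`, `count`.
#' @export
measureGammaTable <- function(camera, powers = seq(0, 1, by = 0.05)) {
  stopifnot(is(camera, "CameraSpec"))
  do.call(rbind, lapply(.CHANNELS, function(ch) {
    cnt <- round(gammaForward(camera@gamma[[ch]], powers))
    data.frame(channel = ch, power = powers, count = as.integer(cnt))
  }))
}

#' Linearize a raw scan stack
#'
#' Inverts the per-channel gamma encoding, mapping every digital count to a
#' normalized linear intensity in `[0, 1]`. Saturated counts (at the
#' curve's saturation level or the bit-depth ceiling) map to 1.0 and are
#' flagged in the saturation mask so that downstream calibration can ignore
#' them.
#'
#' @param stack a [RawScanStack-class].
#' @param curves named list of [GammaCurve-class] objects covering `R`,
#'   `G`, `B` (for example from [fitGammaCurves()]).
#' @return A [LinearScan-class] (sheared; see [deshearStack()]).
#' @export
linearizeStack <- function(stack, curves = stack@camera@gamma) {
  stopifnot(is(stack, "RawScanStack"))
  if (!all(.CHANNELS %in% names(curves)))
    stop("curves must contain one GammaCurve per channel R, G, B")
  mx <- as.integer(2^stack@camera@bitDepth - 1)
  vals <- array(0, dim = dim(stack@counts))
  sat <- array(FALSE, dim = dim(stack@counts))
  for (c in 1:3) {
    inv <- .gammaInverseFun(curves[[.CHANNELS[c]]])
    lut <- inv$invert(0:mx)
    satLut <- (0:mx) >= min(inv$satCount, mx)
    cnt <- stack@counts[, , , c]
    sat[, , , c] <- satLut[cnt + 1L]
    v <- lut[cnt + 1L]
    v[satLut[cnt + 1L]] <- 1.0
    vals[, , , c] <- v
  }
  new("LinearScan", values = vals, saturated = sat, camera = stack@camera,
      scan = stack@scan, scene = stack@scene, desheared = FALSE,
      frameOffset = 0L)
}

#' Read or write a gamma measurement table (CSV)
#'
#' The on-disk characterization format: one row per measurement with
#' columns `channel` (R/G/B), `power` (normalized, `[0, 1]`) and `count`
#' (digital counts).
#'
#' @param path CSV file path.
#' @param table data.frame as returned by [measureGammaTable()].
#' @return `readGammaTable()` returns the data.frame; `writeGammaTable()`
#'   its path, invisibly.
#' @export
readGammaTable <- function(path) {
  if (!file.exists(path)) stop("gamma table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "power", "count")
  if (!all(need %in% names(tab)))
    stop("gamma table must have columns channel, power, count")
  tab
}

#' @rdname readGammaTable
#' @export
writeGammaTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Serialize fitted gamma curves as JSON
#'
#' @param curves named list of [GammaCurve-class] objects.
#' @param path JSON file path.
#' @return `readGammaCurves()` returns the named list;
#'   `writeGammaCurves()` the path, invisibly.
#' @export
writeGammaCurves <- function(curves, path) {
  obj <- lapply(curves, function(cu)
    list(channel = cu@channel,
         power = unname(cu@knots[, 1]), count = unname(cu@knots[, 2])))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGammaCurves
#' @export
readGammaCurves <- function(path) {
  if (!file.exists(path)) stop("gamma curve file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stats::setNames(lapply(obj, function(e)
    new("GammaCurve", channel = e$channel,
        knots = cbind(power = e$power, count = e$count))), names(obj))
}
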
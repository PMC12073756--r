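# Channel trimming/summation and interpolation onto the uniform band grid.

#' @include AllClasses.R specs.R wavelength.R
NULL

#' Trim RGB channels in wavelength and sum them
#'
#' With the filter acting as the wavelength selector, the three RGB channels
#' of a monochromatic (de-sheared) frame all observe the same band; each
#' channel is zeroed outside its usable wavelength window (where it carries
#' only baseline noise) and the trimmed channels are summed into a single
#' total intensity per pixel per frame.
#'
#' @param scan a de-sheared [LinearScan-class].
#' @param map a [WavelengthMap-class] for the same stack (the windows are
#'   expressed in nm, so the map must be estimated first).
#' @param windows named list of `c(min, max)` nm windows per channel; see
#'   [channelTrimWindows()].
#' @return A list (class `monoStack`) with elements `values` (array
#'   `(frame, row, col)`), `lambda` (per-frame wavelength, nm), `saturated`
#'   (logical array flagging pixels whose active channels saturated) and
#'   `scene`.
#' @export
trimAndSumChannels <- function(scan, map, windows = channelTrimWindows()) {
  stopifnot(is(scan, "LinearScan"))
  if (!scan@desheared)
    stop("channel trimming applies to a de-sheared stack")
  if (!is(map, "WavelengthMap"))
    stop("a WavelengthMap is required: trim windows are expressed in nm")
  if (!all(.CHANNELS %in% names(windows)))
    stop("windows must be a named list with entries R, G, B")
  d <- dim(scan@values)
  lam <- framesToWavelength(map, 0:(d[1] - 1))
  vals <- array(0, dim = d[1:3])
  sat <- array(FALSE, dim = d[1:3])
  anyActive <- rep(FALSE, d[1])
  for (c in 1:3) {
    w <- windows[[.CHANNELS[c]]]
    active <- lam >= w[1] & lam <= w[2]
    anyActive <- anyActive | active
    if (!any(active)) next
    vals[active, , ] <- vals[active, , ] + scan@values[active, , , c]
    sat[active, , ] <- sat[active, , ] | scan@saturated[active, , , c]
  }
  # frames with no active channel are flagged: they carry no signal
  sat[!anyActive, , ] <- TRUE
  structure(list(values = vals, lambda = lam, saturated = sat,
                 scene = scan@scene),
            class = "monoStack")
}

#' Default interpolation grid
#'
#' 225 uniformly spaced wavelengths on `[435, 699]` nm: after factor-5
#' binning ([binBands()]) this yields the 45-band spectra the classifier
#' consumes, while honoring the discard rule for bands below 435 and above
#' 699 nm.
#'
#' @param nPoints number of grid points.
#' @param lambdaMin,lambdaMax grid limits in nm.
#' @return Numeric vector of band centers.
#' @export
defaultBandGrid <- function(nPoints = 225, lambdaMin = 435,
                            lambdaMax = 699) {
  seq(lambdaMin, lambdaMax, length.out = nPoints)
}

#' Interpolate frame-sampled intensities onto a uniform wavelength grid
#'
#' Linearly interpolates each pixel's summed intensity from the per-frame
#' wavelengths to the requested band centers. Grid points outside the
#' stack's wavelength coverage, or fed by saturated frames, are marked
#' invalid.
#'
#' @param mono a `monoStack` from [trimAndSumChannels()].
#' @param map the [WavelengthMap-class] used to build it.
#' @param grid band centers in nm, within `[435, 699]`.
#' @return A [Hypercube-class] of pre-calibration intensities.
#' @export
interpolateBands <- function(mono, map, grid = defaultBandGrid()) {
  if (!inherits(mono, "monoStack"))
    stop("mono must come from trimAndSumChannels()")
  if (!is(map, "WavelengthMap")) stop("a WavelengthMap is required")
  if (any(grid < 435 | grid > 699))
    stop("grid must lie within [435, 699] nm (bands outside are discarded)")
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")
  lam <- mono$lambda
  if (max(grid) < lam[1] || min(grid) > lam[length(lam)])
    stop("grid lies entirely outside the scan's wavelength coverage")
  d <- dim(mono$values)
  nB <- length(grid)
  vals <- array(0, dim = c(d[2], d[3], nB))
  valid <- array(FALSE, dim = c(d[2], d[3], nB))
  covered <- grid >= lam[1] & grid <= lam[length(lam)]
  j <- findInterval(grid, lam, rightmost.closed = TRUE)
  for (b in seq_len(nB)) {
    if (!covered[b]) next
    jb <- min(max(j[b], 1L), d[1] - 1L)
    w <- (grid[b] - lam[jb]) / (lam[jb + 1L] - lam[jb])
    vals[, , b] <- (1 - w) * mono$values[jb, , ] + w * mono$values[jb + 1L, , ]
    valid[, , b] <- !(mono$saturated[jb, , ] | mono$saturated[jb + 1L, , ])
  }
  new("Hypercube", values = vals, bandCenters = grid, validMask = valid,
      scene = mono$scene,
      processing = list(wavelengthMap = map, kind = "intensity"))
}
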
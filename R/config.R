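# Pipeline configuration: one validated document holding every module
# default, readable from YAML.

#' @include AllClasses.R specs.R wavelength.R cube.R
NULL

#' Default pipeline configuration
#'
#' All tunable parameters of the simulator, reconstruction and classifier
#' in one nested list: scene geometry, filter and camera optics, scan
#' kinematics, onset threshold, per-channel trim windows (nm), the
#' interpolation grid, Savitzky-Golay settings, the binning factor, the
#' network architecture and the training schedule.
#'
#' @return Nested named list of defaults.
#' @export
pipelineConfig <- function() {
  list(
    scene = list(preset = "four_species", rows = 128, cols = 160,
                 marginRows = 12, flatR = 0.5, greyReflectance = 0.1),
    filter = list(lengthMM = 47.8, cwlStart = 400, cwlEnd = 700,
                  fwhmStart = 3, fwhmEnd = 9, peakTransmittance = 1.0),
    camera = list(frameRate = 240, bitDepth = 8, gammaExponent = 0.45),
    scan = list(nFrames = 240, shiftSlope = 0.2, noiseSd = 0.005),
    onset = list(threshold = 0.1),
    trim = list(red = c(510, 660), green = c(465, 620), blue = c(430, 566)),
    grid = list(nPoints = 225, lambdaMin = 435, lambdaMax = 699),
    calibration = list(rRef = 0.1),
    savgol = list(order = 2, window = 9),
    binning = list(factor = 5),
    model = list(conv1Filters = 32, conv2Filters = 64, kernel = 3,
                 pool = 2, dropout = 0.25, denseUnits = 128),
    training = list(epochs = 300, batchSize = 256, valFraction = 0.1,
                    lr = 1e-3)
  )
}

# Recursively merge user values over defaults, rejecting unknown keys.
.mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown configuration key(s): ",
         paste0(path, bad, collapse = ", "))
  for (nm in names(user)) {
    here <- paste0(path, nm)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration key '", here, "' must be a mapping")
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], user[[nm]],
                                     paste0(here, "."))
    } else {
      v <- user[[nm]]
      if (is.list(v)) v <- unlist(v)
      if (is.character(defaults[[nm]]) != is.character(v))
        stop("configuration key '", here, "' has the wrong type")
      defaults[[nm]] <- v
    }
  }
  defaults
}

#' Read (and validate) a pipeline configuration
#'
#' Loads a YAML document and merges it over [pipelineConfig()]; unknown
#' keys are rejected.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return Validated configuration list.
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- pipelineConfig()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  .mergeConfig(cfg, user)
}

#' @rdname readPipelineConfig
#' @param config configuration list to serialize.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Build spec objects from a configuration.
.specsFromConfig <- function(cfg, seed = 1L) {
  filter <- FilterSpec(lengthMM = cfg$filter$lengthMM,
                       cwlStart = cfg$filter$cwlStart,
                       cwlEnd = cfg$filter$cwlEnd,
                       fwhmStart = cfg$filter$fwhmStart,
                       fwhmEnd = cfg$filter$fwhmEnd,
                       peakTransmittance = cfg$filter$peakTransmittance)
  camera <- CameraSpec(frameRate = cfg$camera$frameRate,
                       bitDepth = cfg$camera$bitDepth,
                       rows = cfg$scene$rows, cols = cfg$scene$cols,
                       gamma = defaultGammaCurves(cfg$camera$gammaExponent))
  scan <- ScanSpec(nFrames = cfg$scan$nFrames,
                   shiftSlope = cfg$scan$shiftSlope,
                   noiseSd = cfg$scan$noiseSd, seed = seed)
  list(filter = filter, camera = camera, scan = scan)
}

.trimFromConfig <- function(cfg) {
  list(R = cfg$trim$red, G = cfg$trim$green, B = cfg$trim$blue)
}

.gridFromConfig <- function(cfg) {
  defaultBandGrid(cfg$grid$nPoints, cfg$grid$lambdaMin, cfg$grid$lambdaMax)
}
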
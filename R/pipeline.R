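# End-to-end reconstruction: raw stack -> calibrated, denoised, binned
# 45-band reflectance hypercube; and the full simulate/train/evaluate demo.

#' @include AllClasses.R specs.R gamma.R shift.R wavelength.R cube.R
#' @include calibrate.R library.R train.R metrics.R config.R
NULL

#' Reconstruct a reflectance hypercube from a raw scan
#'
#' Runs the complete pre-processing chain: gamma linearization, row-shift
#' estimation on grey-margin traces, de-shearing into monochromatic frames,
#' onset detection, the frame-to-wavelength map, channel trimming and
#' summation, interpolation onto the uniform band grid, reflectance
#' calibration against the grey plate, Savitzky-Golay denoising and
#' spectral binning. The wavelength map is estimated before nm-trimming
#' (the trim windows are expressed in nm, so the map must exist first);
#' onsets are detected on untrimmed grey traces.
#'
#' @param stack a [RawScanStack-class].
#' @param gammaCurves per-channel [GammaCurve-class] list; defaults to the
#'   camera's own curves (for real data, fit them from a measurement table
#'   with [fitGammaCurves()]).
#' @param greyRegion grey-plate region for onsets and calibration (see
#'   [calibrateReflectance()]); defaults to the scene's grey pixels.
#' @param config pipeline configuration (see [pipelineConfig()]); supplies
#'   the onset threshold, trim windows, grid, calibration reference,
#'   Savitzky-Golay and binning settings.
#' @param shiftModel optional pre-estimated [ShiftModel-class]; when `NULL`
#'   it is estimated from the grey margins.
#' @return The final binned reflectance [Hypercube-class]; its
#'   `processing` slot records the shift model, wavelength map and
#'   calibration.
#' @examples
#' sc <- makeScene("flat_patch", rows = 48, cols = 40, marginRows = 8)
#' cam <- CameraSpec(rows = 48, cols = 40)
#' stk <- renderScan(sc, cam, scan = ScanSpec(nFrames = 160, seed = 2))
#' cube <- buildCube(stk)
#' nBands(cube)  # 45
#' @export
buildCube <- function(stack, gammaCurves = stack@camera@gamma,
                      greyRegion = NULL, config = pipelineConfig(),
                      shiftModel = NULL) {
  stopifnot(is(stack, "RawScanStack"))
  lin <- linearizeStack(stack, gammaCurves)
  if (is.null(shiftModel))
    shiftModel <- estimateShiftModel(lin)
  mono <- deshearStack(lin, shiftModel)
  onsets <- detectOnsets(mono, greyRegion = greyRegion,
                         threshold = config$onset$threshold)
  wmap <- buildWavelengthMap(onsets)
  summed <- trimAndSumChannels(mono, wmap, windows = .trimFromConfig(config))
  cube <- interpolateBands(summed, wmap, grid = .gridFromConfig(config))
  cube <- calibrateReflectance(cube, greyRegion = greyRegion,
                               rRef = config$calibration$rRef)
  cube <- savgolDenoise(cube, order = config$savgol$order,
                        window = config$savgol$window)
  cube <- binBands(cube, factor = config$binning$factor)
  cube@processing$shiftModel <- shiftModel
  cube
}

#' Simulate, reconstruct, train and evaluate end to end
#'
#' The package's integration demo on purely synthetic data: renders
#' training scans of the four-species scene (patch placement permuted per
#' scan seed), reconstructs their hypercubes, extracts labeled pixels from
#' ground-truth-derived annotations, trains the 1D-CNN, and evaluates
#' pixelwise segmentation on a held-out scan rendered with a different
#' seed. Fully deterministic for a fixed `seed`.
#'
#' @param seed master seed; scan seeds and training seeds derive from it.
#' @param config pipeline configuration (see [pipelineConfig()]).
#' @param epochs training epochs (overrides `config$training$epochs`).
#' @param nTrainScans rendered training scans.
#' @param verbose print progress messages.
#' @return list with `metrics` ([ClassMetrics-class]), `model`
#'   ([ConvNet1D-class]), `coverage` (held-out cube coverage fractions),
#'   `library` sizes and the held-out `cube`.
#' @export
fullDemo <- function(seed = 1L, config = pipelineConfig(), epochs = NULL,
                     nTrainScans = 2L, verbose = FALSE) {
  seed <- as.integer(seed)
  if (is.null(epochs)) epochs <- config$training$epochs
  say <- function(...) if (verbose) message(...)
  sim <- function(scanSeed) {
    sp <- .specsFromConfig(config, seed = scanSeed)
    scene <- makeScene(config$scene$preset, rows = config$scene$rows,
                       cols = config$scene$cols,
                       marginRows = config$scene$marginRows,
                       greyReflectance = config$scene$greyReflectance,
                       seed = scanSeed)
    renderScan(scene, sp$camera, sp$filter, sp$scan)
  }
  cubes <- list(); anns <- list()
  for (i in seq_len(nTrainScans)) {
    id <- paste0("train", i)
    say("rendering + reconstructing ", id)
    stk <- sim(seed + i - 1L)
    cubes[[id]] <- buildCube(stk, config = config)
    anns[[id]] <- annotationsFromScene(stk@scene, id)
  }
  say("extracting labeled pixels")
  lib <- extractLabeledPixels(cubes, do.call(rbind, anns))
  model <- buildModel(nBands = length(.gridFromConfig(config)) %/%
                        config$binning$factor,
                      classLabels = c(sort(unique(
                        setdiff(lib@info$class, "grey"))), "grey"),
                      conv1Filters = config$model$conv1Filters,
                      conv2Filters = config$model$conv2Filters,
                      kernel = config$model$kernel,
                      pool = config$model$pool,
                      dropout = config$model$dropout,
                      denseUnits = config$model$denseUnits,
                      seed = seed)
  say("training (", epochs, " epochs)")
  model <- trainModel(model, lib, epochs = epochs,
                      batchSize = config$training$batchSize,
                      valFraction = config$training$valFraction,
                      lr = config$training$lr, seed = seed,
                      verbose = verbose)
  say("evaluating on a held-out scan")
  heldOut <- sim(seed + nTrainScans)
  cube <- buildCube(heldOut, config = config)
  pred <- predictCube(model, cube)
  annEval <- annotationsFromScene(heldOut@scene, "heldout")
  metrics <- evaluateSegmentation(pred, annEval)
  list(metrics = metrics, model = model, coverage = pred$coverage,
       libraryCounts = table(lib@info$class), cube = cube, pred = pred)
}
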
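# Container formats: raw scans and cubes as gzip-compressed binary arrays
# with JSON metadata sidecars, plus PNG frame-directory import.

#' @include AllClasses.R specs.R gamma.R
NULL

.cameraToList <- function(camera) {
  list(frameRate = camera@frameRate, bitDepth = camera@bitDepth,
       rows = camera@rows, cols = camera@cols,
       gamma = lapply(camera@gamma, function(cu)
         list(channel = cu@channel, power = unname(cu@knots[, 1]),
              count = unname(cu@knots[, 2]))),
       sensMean = as.list(camera@sensMean),
       sensSd = as.list(camera@sensSd),
       gain = camera@gain)
}

.cameraFromList <- function(x) {
  CameraSpec(frameRate = x$frameRate, bitDepth = x$bitDepth, rows = x$rows,
             cols = x$cols,
             gamma = stats::setNames(lapply(x$gamma, function(e)
               new("GammaCurve", channel = e$channel,
                   knots = cbind(power = unlist(e$power),
                                 count = unlist(e$count)))),
               names(x$gamma)),
             sensMean = unlist(x$sensMean)[.CHANNELS],
             sensSd = unlist(x$sensSd)[.CHANNELS],
             gain = if (is.null(x$gain) || !length(x$gain))
               NA_real_ else as.numeric(x$gain))
}

#' Write or read a raw scan container
#'
#' Stores the 4-D count stack as gzip-compressed bytes (`<path>.bin.gz`,
#' one byte per count for 8-bit data, frame-major order) with a JSON
#' sidecar (`<path>.json`) holding the dimensions and the camera/scan
#' metadata. For simulated scans the sidecar also records the ground-truth
#' label map, class names and margin, so that a scan re-read from disk
#' reconstructs its [SceneSpec-class] when the class spectra are the
#' built-in [referenceSpectrum()] ones.
#'
#' @param stack a [RawScanStack-class].
#' @param path path prefix (no extension).
#' @return `writeRawScan()` the prefix, invisibly; `readRawScan()` the
#'   restored [RawScanStack-class].
#' @export
writeRawScan <- function(stack, path) {
  stopifnot(is(stack, "RawScanStack"))
  if (stack@camera@bitDepth > 8)
    stop("the container stores one byte per count (8-bit data)")
  meta <- list(
    dims = dim(stack@counts),
    camera = .cameraToList(stack@camera),
    scan = list(nFrames = stack@scan@nFrames,
                shiftSlope = stack@scan@shiftSlope,
                noiseSd = stack@scan@noiseSd, seed = stack@scan@seed)
  )
  if (!is.null(stack@scene)) {
    sc <- stack@scene
    known <- vapply(c("grey", sc@classNames), function(nm)
      nm %in% c(names(.spectrumDips), "grey"), logical(1))
    meta$groundTruth <- list(
      labelMap = as.vector(sc@labelMap), classNames = sc@classNames,
      greyReflectance = sc@greyReflectance, marginRows = sc@marginRows,
      builtinSpectra = all(known))
  }
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, na = "null")
  con <- gzfile(paste0(path, ".bin.gz"), "wb")
  on.exit(close(con))
  writeBin(as.raw(stack@counts), con)
  invisible(path)
}

#' @rdname writeRawScan
#' @export
readRawScan <- function(path) {
  jsonPath <- paste0(path, ".json"); binPath <- paste0(path, ".bin.gz")
  if (!file.exists(jsonPath) || !file.exists(binPath))
    stop("raw scan container not found at prefix: ", path)
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  dims <- unlist(meta$dims)
  con <- gzfile(binPath, "rb")
  on.exit(close(con))
  bytes <- readBin(con, "raw", n = prod(dims) + 1L)
  if (length(bytes) != prod(dims))
    stop("raw scan payload size does not match the sidecar dimensions")
  counts <- array(as.integer(bytes), dim = dims)
  camera <- .cameraFromList(meta$camera)
  scan <- ScanSpec(nFrames = meta$scan$nFrames,
                   shiftSlope = meta$scan$shiftSlope,
                   noiseSd = meta$scan$noiseSd, seed = meta$scan$seed)
  scene <- NULL
  gt <- meta$groundTruth
  if (!is.null(gt) && isTRUE(gt$builtinSpectra)) {
    lm <- matrix(as.integer(unlist(gt$labelMap)), dims[2], dims[3])
    classes <- stats::setNames(
      lapply(gt$classNames, referenceSpectrum), gt$classNames)
    scene <- makeScene(lm, classes = classes,
                       marginRows = gt$marginRows,
                       greyReflectance = gt$greyReflectance)
  }
  new("RawScanStack", counts = counts, camera = camera, scan = scan,
      scene = scene)
}

#' Import a raw scan from a directory of numbered PNG frames
#'
#' Reads `frame-0001.png, frame-0002.png, ...` (any shared prefix;
#' lexicographic order) as 8-bit RGB frames. Requires the `png` package.
#'
#' @param dir directory of PNG frames.
#' @param camera a [CameraSpec-class] matching the frame geometry.
#' @param scan a [ScanSpec-class] (its `nFrames` must equal the number of
#'   files).
#' @return A [RawScanStack-class] (`scene = NULL`).
#' @export
readRawScanPNG <- function(dir, camera, scan) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("reading PNG frames requires the 'png' package")
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames found in ", dir)
  if (length(files) != scan@nFrames)
    stop("found ", length(files), " frames but scan@nFrames = ",
         scan@nFrames)
  counts <- array(0L, dim = c(length(files), camera@rows, camera@cols, 3L))
  for (i in seq_along(files)) {
    img <- png::readPNG(files[i])
    if (length(dim(img)) != 3 || dim(img)[3] < 3)
      stop("frame ", files[i], " is not an RGB image")
    if (dim(img)[1] != camera@rows || dim(img)[2] != camera@cols)
      stop("frame ", files[i], " does not match the camera geometry")
    counts[i, , , ] <- as.integer(round(img[, , c(1, 2, 3)] * 255))
  }
  new("RawScanStack", counts = counts, camera = camera, scan = scan,
      scene = NULL)
}

#' Write or read a hypercube container
#'
#' Lossless twin of the ENVI export: values and mask as gzip-compressed
#' doubles/bytes (`<path>.cube.gz`) with a JSON sidecar carrying dimensions
#' and band centers.
#'
#' @param cube a [Hypercube-class].
#' @param path path prefix (no extension).
#' @return `writeCube()` the prefix, invisibly; `readCube()` the restored
#'   [Hypercube-class].
#' @export
writeCube <- function(cube, path) {
  stopifnot(is(cube, "Hypercube"))
  meta <- list(dims = dim(cube@values),
               bandCenters = cube@bandCenters)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  con <- gzfile(paste0(path, ".cube.gz"), "wb")
  on.exit(close(con))
  writeBin(as.vector(cube@values), con, size = 8, endian = "little")
  writeBin(as.integer(cube@validMask), con, size = 1)
  invisible(path)
}

#' @rdname writeCube
#' @export
readCube <- function(path) {
  jsonPath <- paste0(path, ".json"); binPath <- paste0(path, ".cube.gz")
  if (!file.exists(jsonPath) || !file.exists(binPath))
    stop("cube container not found at prefix: ", path)
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  dims <- unlist(meta$dims)
  n <- prod(dims)
  con <- gzfile(binPath, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = 8, endian = "little")
  m <- readBin(con, "integer", n = n, size = 1, signed = FALSE)
  if (length(v) != n || length(m) != n)
    stop("cube payload size does not match the sidecar dimensions")
  new("Hypercube", values = array(v, dims),
      bandCenters = unlist(meta$bandCenters),
      validMask = array(m > 0, dims), scene = NULL,
      processing = list(source = binPath))
}
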
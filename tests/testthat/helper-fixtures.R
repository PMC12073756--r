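# Shared fixtures, built once per test session and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small four-species scan + cube: fast enough for unit tests.
smallScan <- function() fixture("smallScan", {
  scene <- makeScene("four_species", rows = 64, cols = 80, marginRows = 8,
                     seed = 3)
  cam <- CameraSpec(rows = 64, cols = 80)
  renderScan(scene, cam, FilterSpec(),
             ScanSpec(nFrames = 150, shiftSlope = 0.2, noiseSd = 0.005,
                      seed = 5))
})

smallCube <- function() fixture("smallCube", buildCube(smallScan()))

smallLibrary <- function() fixture("smallLibrary", {
  ann <- annotationsFromScene(smallScan()@scene, "small")
  extractLabeledPixels(smallCube(), ann)
})

# Full-size four-species scan + cube (the study's default geometry).
defaultScan <- function() fixture("defaultScan", {
  scene <- makeScene("four_species", seed = 1)
  renderScan(scene, CameraSpec(), FilterSpec(), ScanSpec(seed = 101))
})

defaultCube <- function() fixture("defaultCube", buildCube(defaultScan()))

# Full-size flat R = 0.5 patch at the prescribed noise level.
flatScan <- function() fixture("flatScan", {
  scene <- makeScene("flat_patch", flatR = 0.5)
  renderScan(scene, CameraSpec(), FilterSpec(),
             ScanSpec(noiseSd = 0.005, seed = 202))
})

# Tiny synthetic two-class library for classifier unit tests (separable).
tinyLibrary <- function(n = 300, nBands = 45, seed = 42) {
  set.seed(seed)
  X1 <- matrix(stats::rnorm(n * nBands, 0.20, 0.02), n, nBands)
  X2 <- matrix(stats::rnorm(n * nBands, 0.20, 0.02), n, nBands)
  X2[, 10:20] <- X2[, 10:20] - 0.08
  new("SpectralLibrary",
      spectra = rbind(X1, X2),
      info = data.frame(cubeId = "tiny", row = seq_len(2 * n), col = 1L,
                        class = rep(c("a", "b"), each = n),
                        stringsAsFactors = FALSE),
      bandCenters = seq(440, 698, length.out = nBands))
}

# Synthetic hypercube with explicit values (all bands valid).
syntheticCube <- function(values, bandCenters = NULL) {
  d <- dim(values)
  if (is.null(bandCenters)) bandCenters <- seq(440, 690, length.out = d[3])
  new("Hypercube", values = values, bandCenters = bandCenters,
      validMask = array(TRUE, d), scene = NULL, processing = list())
}
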
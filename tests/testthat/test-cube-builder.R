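# Shift estimation, de-shearing, onsets, wavelength map, trimming and
# band interpolation.

# LinearScan with a prescribed per-row trace shift. Deeper rows see each
# feature earlier (as the moving filter does), so row y's trace is
# base(f + lag(y)), all channels alike.
shiftedScan <- function(nF, rows, cols, lagFun, seedNoise = 0) {
  base <- function(f) exp(-(f - nF / 2)^2 / (2 * (nF / 8)^2))
  vals <- array(0, dim = c(nF, rows, cols, 3))
  for (y in seq_len(rows))
    vals[, y, , ] <- base(seq_len(nF) + lagFun(y))
  if (seedNoise > 0) {
    set.seed(1)
    vals <- vals + array(stats::rnorm(length(vals), sd = seedNoise),
                         dim = dim(vals))
  }
  new("LinearScan", values = vals, saturated = array(FALSE, dim(vals)),
      camera = CameraSpec(rows = rows, cols = cols),
      scan = ScanSpec(nFrames = nF), scene = NULL, desheared = FALSE,
      frameOffset = 0L)
}

test_that("row-shift estimation recovers known lags", {
  sc <- shiftedScan(120, 10, 4, function(y) 0)
  expect_equal(estimateRowShift(sc, 1, 1, 10), 0, tolerance = 1e-6)
  # exact 7-frame shift between the two rows, against brute-force truth
  sc7 <- shiftedScan(120, 10, 4, function(y) ifelse(y > 5, 7, 0))
  expect_equal(estimateRowShift(sc7, 2, 1, 10), 7, tolerance = 0.05)
  # flat trace errors
  scFlat <- shiftedScan(120, 10, 4, function(y) 0)
  scFlat@values[, 3, , ] <- 0.5
  expect_error(estimateRowShift(scFlat, 1, 3, 10), "flat")
})

test_that("row shift from a simulated scan matches the scan spec within 2%", {
  lin <- linearizeStack(smallScan())
  m <- smallScan()@scene@marginRows
  rowTop <- 4L; rowBottom <- 61L
  lag <- estimateRowShift(lin, 40, rowTop, rowBottom)
  expect_equal(lag / (rowBottom - rowTop), 0.2, tolerance = 0.02)
})

test_that("shift model fitting matches the closed-form least squares", {
  expect_equal(shiftSlope(fitShiftModel(100, 25)), 0.25)
  dr <- c(40, 60, 80, 100)
  expect_equal(shiftSlope(fitShiftModel(dr, 0.1 * dr)), 0.1)
  set.seed(7)
  lags <- 0.17 * dr + stats::rnorm(4, sd = 0.3)
  expect_equal(shiftSlope(fitShiftModel(dr, lags)),
               sum(dr * lags) / sum(dr^2))
  expect_error(fitShiftModel(c(0, 0), c(1, 2)), "degenerate")
})

test_that("de-shearing removes the shear and keeps the frame budget", {
  # identity when the slope is zero
  sc <- shiftedScan(60, 8, 3, function(y) 0)
  out <- deshearStack(sc, new("ShiftModel", slope = 0, referenceRow = 1))
  expect_equal(out@values, sc@values)
  expect_equal(out@frameOffset, 0L)
  # frame budget: n_frames - ceil(slope * (rows - 1)) frames survive
  sc2 <- shiftedScan(240, 128, 2, function(y) 0.2 * (y - 1))
  out2 <- deshearStack(sc2, new("ShiftModel", slope = 0.2,
                                referenceRow = 1))
  expect_gte(dim(out2@values)[1], 240 - ceiling(0.2 * 128))
  # residual lag after de-shearing a simulated scan is below one frame
  lin <- linearizeStack(smallScan())
  model <- estimateShiftModel(lin)
  mono <- deshearStack(lin, model)
  residual <- estimateRowShift(mono, 40, 4, 61)
  expect_lt(abs(residual), 1)
  # re-estimated slope on the de-sheared stack is essentially zero
  expect_lt(abs(shiftSlope(estimateShiftModel(mono))) * 57, 1)
  expect_error(
    deshearStack(sc, new("ShiftModel", slope = 100, referenceRow = 1)),
    "no frame")
})

test_that("onset detection finds threshold crossings on grey traces", {
  nF <- 250
  tr <- matrix(0, nF, 3, dimnames = list(NULL, c("R", "G", "B")))
  # blue rises at frame 40 (0-based), red stays above threshold up to 201
  tr[41:nF, "B"] <- 1
  tr[1:202, "R"] <- 1
  tr[, "G"] <- 0.5
  on <- detectOnsets(tr)
  expect_equal(unname(on["blue"]), 40)
  expect_equal(unname(on["red"]), 201)
  # linear-scan oracle: first/last indices above theta * max
  theta <- 0.1
  expect_equal(unname(on["blue"]),
               which(tr[, "B"] >= theta * max(tr[, "B"]))[1] - 1)
  tr0 <- tr; tr0[, "B"] <- 0
  expect_error(detectOnsets(tr0), "never crosses")
})

test_that("the wavelength map reproduces its anchors exactly", {
  m <- buildWavelengthMap(c(blue = 100, red = 306))
  expect_identical(m@mLambda, 1.0)
  expect_identical(m@bLambda, 336)
  expect_identical(framesToWavelength(m, 100), 436)
  expect_identical(framesToWavelength(m, 306), 642)
  expect_equal(framesToWavelength(m, 150), 486)
  m2 <- buildWavelengthMap(c(blue = 0, red = 206))
  expect_equal(m2@mLambda, 1.0)
  expect_equal(m2@bLambda, 436)
  expect_error(buildWavelengthMap(c(blue = 50, red = 50)), "equal onsets")
  expect_error(buildWavelengthMap(c(blue = 60, red = 50)),
               "negative dispersion")
})

test_that("channel trimming zeroes out-of-window channels before summing", {
  # three frames at 450 / 550 / 680 nm via a map with m = 115, b = 450...
  nF <- 3
  vals <- array(1, dim = c(nF, 4, 2, 3))
  sc <- new("LinearScan", values = vals,
            saturated = array(FALSE, dim(vals)),
            camera = CameraSpec(rows = 4, cols = 2),
            scan = ScanSpec(nFrames = 3), scene = NULL, desheared = TRUE,
            frameOffset = 0L)
  map <- new("WavelengthMap", mLambda = 115, bLambda = 450,
             frameBlueOnset = 0, frameRedOnset = 1,
             lambdaBlue = 450, lambdaRed = 565)
  mono <- trimAndSumChannels(sc, map)
  expect_equal(mono$lambda, c(450, 565, 680))
  # 450 nm: blue only; 565 nm: blue + green + red; 680 nm: nothing
  expect_true(all(mono$values[1, , ] == 1))
  expect_true(all(mono$values[2, , ] == 3))
  expect_true(all(mono$values[3, , ] == 0))
  expect_true(all(mono$saturated[3, , ]))
  expect_error(trimAndSumChannels(sc, NULL), "WavelengthMap")
  # all-zero stack stays zero
  sc0 <- sc; sc0@values[] <- 0
  expect_true(all(trimAndSumChannels(sc0, map)$values == 0))
})

test_that("band interpolation is exact at knots and linear between them", {
  nF <- 5
  vals <- array(0, dim = c(nF, 4, 2, 3))
  for (f in seq_len(nF)) vals[f, , , ] <- f
  sc <- new("LinearScan", values = vals,
            saturated = array(FALSE, dim(vals)),
            camera = CameraSpec(rows = 4, cols = 2),
            scan = ScanSpec(nFrames = 5), scene = NULL, desheared = TRUE,
            frameOffset = 0L)
  map <- new("WavelengthMap", mLambda = 50, bLambda = 450,
             frameBlueOnset = 0, frameRedOnset = 1,
             lambdaBlue = 450, lambdaRed = 500)
  mono <- trimAndSumChannels(sc, map)   # frames at 450..650 nm
  cube <- interpolateBands(mono, map, grid = c(450, 475, 500, 650))
  # knot: frame 1 (450 nm) summed value = blue only = 1
  expect_equal(cube@values[1, 1, 1], 1)
  # midpoint 475 nm between frames at 450 and 500
  expect_equal(cube@values[1, 1, 2],
               mean(c(mono$values[1, 1, 1], mono$values[2, 1, 1])))
  expect_error(interpolateBands(mono, map, grid = c(420, 500)),
               "\\[435, 699\\]")
  g <- defaultBandGrid()
  expect_gte(min(g), 435)
  expect_lte(max(g), 699)
  expect_length(g, 225)
})

test_that("reconstructed spectra localize pigment dips within a band", {
  lib <- smallLibrary()
  cube <- smallCube()
  cm <- classMeanSpectra(lib)
  valid <- apply(validMask(cube), 3, any)
  bc <- cm$bandCenters[valid]
  spacing <- diff(bc)[1]
  mins <- findAbsorptionMinima(cm$mean["brown_a", valid],
                               list(c(430, 470), c(620, 660)), bc)
  expect_lt(abs(mins[[1]] - 445), spacing + 1e-9)
  expect_lt(abs(mins[[2]] - 641), spacing + 1e-9)
  minsRed <- findAbsorptionMinima(cm$mean["red_a", valid],
                                  list(c(620, 660)), bc)
  expect_lt(abs(minsRed[[1]] - 639), spacing + 1e-9)
})
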
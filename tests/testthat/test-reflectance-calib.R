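# Reflectance calibration, Savitzky-Golay denoising and band binning.

test_that("calibration scales by the per-band grey mean", {
  vals <- array(0, dim = c(4, 4, 3))
  vals[, , 1] <- 2; vals[, , 2] <- 4; vals[, , 3] <- 8
  vals[1, 1, ] <- 2 * vals[1, 1, ]   # one pixel at twice the grey level
  cube <- syntheticCube(vals)
  cal <- calibrateReflectance(cube, greyRegion = c(2, 4, 1, 4), rRef = 0.1)
  # a pixel equal to the grey mean reads exactly R = 0.1; twice reads 0.2
  expect_equal(cal@values[2, 2, ], c(0.1, 0.1, 0.1))
  expect_equal(cal@values[1, 1, ], c(0.2, 0.2, 0.2))
  # zero grey band is masked invalid
  vals0 <- vals; vals0[, , 2] <- 0
  cal0 <- calibrateReflectance(syntheticCube(vals0),
                               greyRegion = c(2, 4, 1, 4))
  expect_false(any(cal0@validMask[, , 2]))
  expect_true(all(cal0@validMask[, , c(1, 3)]))
  expect_error(calibrateReflectance(cube,
                                    greyRegion = matrix(FALSE, 4, 4)),
               "empty")
})

test_that("grey self-consistency holds exactly after calibration", {
  set.seed(11)
  vals <- array(stats::rexp(6 * 5 * 8, rate = 2), dim = c(6, 5, 8))
  cube <- syntheticCube(vals)
  grey <- matrix(FALSE, 6, 5); grey[1:2, ] <- TRUE
  cal <- calibrateReflectance(cube, greyRegion = grey, rRef = 0.1)
  gm <- apply(cal@values, 3, function(sl) mean(sl[grey]))
  expect_equal(gm, rep(0.1, 8), tolerance = 1e-12)
})

test_that("calibration cancels the illumination spectrum", {
  mk <- function(illum) {
    scene <- makeScene("flat_patch", rows = 40, cols = 32, marginRows = 6,
                       flatR = 0.5, illumination = illum)
    cam <- CameraSpec(rows = 40, cols = 32)
    stk <- renderScan(scene, cam, FilterSpec(),
                      ScanSpec(nFrames = 120, shiftSlope = 0.2,
                               noiseSd = 0, seed = 3))
    buildCube(stk)
  }
  c1 <- mk(function(l) rep(1, length(l)))
  c2 <- mk(function(l) 0.5 + (l - 400) / 400)   # sloped illumination
  interior <- bandCenters(c1) >= 445 & bandCenters(c1) <= 655
  ok <- c1@validMask & c2@validMask
  ok[, , !interior] <- FALSE
  expect_gt(mean(ok), 0.7)
  expect_lt(max(abs(c1@values[ok] - c2@values[ok])), 0.02)
})

test_that("Savitzky-Golay smoothing preserves low-order polynomials", {
  b <- seq_len(45)
  flat <- syntheticCube(array(rep(0.3, 4 * 3 * 45), dim = c(4, 3, 45)))
  expect_equal(savgolDenoise(flat)@values, flat@values, tolerance = 1e-12)
  quadVec <- 0.2 + 0.01 * b - 1e-4 * b^2
  quad <- syntheticCube(aperm(array(quadVec, dim = c(45, 4, 3)),
                              c(2, 3, 1)))
  sm <- savgolDenoise(quad, order = 2, window = 9)
  expect_equal(sm@values, quad@values, tolerance = 1e-12)
  expect_error(savgolDenoise(flat, order = 2, window = 8), "odd")
  expect_error(savgolDenoise(syntheticCube(array(1, c(2, 2, 5))),
                             order = 2, window = 9), "fewer")
})

test_that("Savitzky-Golay matches the reference filter and reduces noise", {
  set.seed(21)
  base <- 0.3 + 0.1 * sin(seq(0, 3, length.out = 45))
  noise <- matrix(stats::rnorm(45 * 20, sd = 0.02), 20, 45)
  spectra <- sweep(noise, 2, base, "+")
  vals <- aperm(array(t(spectra), dim = c(45, 20, 1)), c(2, 3, 1))
  sm <- savgolDenoise(syntheticCube(vals), order = 2, window = 9)
  # independent oracle: signal::sgolayfilt applied spectrum by spectrum
  for (i in c(1, 7, 20))
    expect_equal(sm@values[i, 1, ],
                 as.vector(signal::sgolayfilt(spectra[i, ], p = 2, n = 9)),
                 tolerance = 1e-10)
  resid <- function(x) x - outer(rep(1, nrow(x)), base)
  expect_lt(mean(resid(matrix(sm@values, 20, 45))[, 5:41]^2),
            mean(resid(spectra)[, 5:41]^2))
})

test_that("band binning averages groups and keeps the spectrum mean", {
  set.seed(3)
  vals <- array(stats::runif(3 * 2 * 225), dim = c(3, 2, 225))
  cube <- syntheticCube(vals, bandCenters = defaultBandGrid())
  binned <- binBands(cube, factor = 5)
  expect_equal(nBands(binned), 45)
  expect_equal(mean(binned@values[2, 1, ]), mean(vals[2, 1, ]),
               tolerance = 1e-12)
  grp <- rep(seq_len(45), each = 5)
  expect_equal(binned@bandCenters,
               as.vector(tapply(defaultBandGrid(), grp, mean)))
  expect_equal(binned@values[1, 1, 3], mean(vals[1, 1, 11:15]))
  # identity and invariance cases
  expect_identical(binBands(cube, 1), cube)
  flat <- syntheticCube(array(0.1, dim = c(2, 2, 10)))
  expect_true(all(binBands(flat, 5)@values == 0.1))
  expect_error(binBands(syntheticCube(array(1, c(2, 2, 7))), 5),
               "divisible")
  # masked members are excluded from the average
  m <- syntheticCube(array(1, dim = c(1, 1, 10)))
  m@values[1, 1, 1:5] <- c(1, 1, 1, 9, 9)
  m@validMask[1, 1, 4:5] <- FALSE
  bm <- binBands(m, 5)
  expect_equal(bm@values[1, 1, 1], 1)
  expect_true(bm@validMask[1, 1, 1])
})
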
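# Gamma characterization, linearization and round trips.

test_that("a linear sensor yields an identity gamma curve", {
  p <- seq(0, 1, by = 0.1)
  cu <- fitGamma(p, 255 * p, channel = "G")
  expect_s4_class(cu, "GammaCurve")
  expect_equal(gammaForward(cu, 0.5), 127.5, tolerance = 1e-9)
  expect_equal(gammaInverse(cu, 128), 128 / 255, tolerance = 1e-6)
})

test_that("saturating measurements produce a flagged, clipped inverse", {
  p <- seq(0, 1, by = 0.1)
  cnt <- pmin(255, round(255 * p / 0.6))  # saturates at 255 for p >= 0.6
  cu <- fitGamma(p, cnt, channel = "R")
  expect_equal(max(cu@knots[, 2]), 255)
  stack <- new("RawScanStack",
               counts = array(255L, dim = c(2, 4, 4, 3)),
               camera = CameraSpec(rows = 4, cols = 4,
                                   gamma = list(R = cu, G = cu, B = cu)),
               scan = ScanSpec(nFrames = 2), scene = NULL)
  lin <- linearizeStack(stack)
  expect_true(all(lin@values == 1.0))
  expect_true(all(lin@saturated))
})

test_that("the fitted inverse recovers power within 1/255 at every knot", {
  p <- seq(0, 1, by = 0.05)
  cnt <- 255 * p^0.45
  cu <- fitGamma(p, cnt, channel = "B")
  rec <- gammaInverse(cu, cnt)
  expect_true(all(abs(rec - p) <= 1 / 255))
})

test_that("gamma fitting validates and projects its inputs", {
  expect_error(fitGamma(c(0, 1), c(0, 255)), ">= 3")
  expect_warning(fitGamma(c(0, 0.3, 0.6, 1), c(0, 120, 80, 255)),
                 "isotonic")
  # monotonicity of the LUT: linearization never reverses count order
  cu <- fitGamma(seq(0, 1, by = 0.05), 255 * seq(0, 1, by = 0.05)^0.45)
  lut <- gammaInverse(cu, 0:255)
  expect_true(all(diff(lut) >= 0))
})

test_that("identity-gamma linearization maps counts to count/255", {
  p <- seq(0, 1, by = 0.1)
  cu <- fitGamma(p, 255 * p, channel = "R")
  curves <- list(R = cu,
                 G = fitGamma(p, 255 * p, channel = "G"),
                 B = fitGamma(p, 255 * p, channel = "B"))
  cnt <- array(128L, dim = c(2, 4, 4, 3))
  stack <- new("RawScanStack", counts = cnt,
               camera = CameraSpec(rows = 4, cols = 4, gamma = curves),
               scan = ScanSpec(nFrames = 2), scene = NULL)
  lin <- linearizeStack(stack, curves)
  expect_equal(lin@values, array(128 / 255, dim(cnt)), tolerance = 1e-6)
  expect_false(any(lin@saturated))
  expect_error(linearizeStack(stack, curves["R"]), "per channel")
})

test_that("forward gamma then linearization round-trips within quantization", {
  cam <- CameraSpec(rows = 8, cols = 8)
  x <- seq(0.02, 0.95, length.out = 200)
  for (ch in c("R", "G", "B")) {
    cu <- cam@gamma[[ch]]
    cnt <- round(gammaForward(cu, x))
    rec <- gammaInverse(cu, cnt)
    # quantization bound: half a count through the inverse slope, plus the
    # fit tolerance
    expect_true(all(abs(rec - x) <= 2 / 255))
    expect_true(all(diff(rec[order(x)]) >= -1e-12))
  }
})

test_that("render-linearize agrees with the noise-free linear render", {
  scene <- makeScene("four_species", rows = 48, cols = 60, marginRows = 6,
                     seed = 2)
  cam <- CameraSpec(rows = 48, cols = 60)
  scan <- ScanSpec(nFrames = 100, shiftSlope = 0.2, noiseSd = 0, seed = 2)
  stk <- renderScan(scene, cam, FilterSpec(), scan)
  linTrue <- renderScan(scene, cam, FilterSpec(), scan, output = "linear")
  # gamma curves re-fitted from a synthetic characterization table, as the
  # physical procedure would produce them
  curves <- fitGammaCurves(measureGammaTable(cam))
  lin <- linearizeStack(stk, curves)
  ok <- !lin@saturated
  expect_gt(mean(ok), 0.99)
  expect_true(all(abs(lin@values[ok] - linTrue[ok]) <= 2 / 255))
})

test_that("gamma tables round-trip through CSV", {
  tab <- measureGammaTable(CameraSpec())
  path <- tempfile(fileext = ".csv")
  writeGammaTable(tab, path)
  back <- readGammaTable(path)
  expect_equal(back$count, tab$count)
  expect_equal(back$power, tab$power)
  expect_equal(back$channel, tab$channel)
  curves <- fitGammaCurves(back)
  expect_named(curves, c("R", "G", "B"))
  jpath <- tempfile(fileext = ".json")
  writeGammaCurves(curves, jpath)
  back2 <- readGammaCurves(jpath)
  expect_equal(back2$G@knots, curves$G@knots, tolerance = 1e-12)
  expect_error(readGammaTable(tempfile()), "not found")
})
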
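# Forward model: filter transmission, reference spectra, scenes, rendering.

test_that("filter transmission follows the linear CWL/FWHM gradients", {
  f <- FilterSpec()
  # band center at each end and at the midpoint (two-point line: 550 nm)
  expect_equal(filterTransmission(f, 0, 400), 1.0)
  expect_equal(filterTransmission(f, 1, 700), 1.0)
  cwlFit <- unname(stats::lm(c(400, 700) ~ c(0, 1))$coefficients)
  expect_equal(cwlFit[1] + 0.5 * cwlFit[2], 550)
  expect_equal(filterTransmission(f, 0.5, 550), 1.0)
  # half maximum at +/- FWHM/2 (9 nm at the red end)
  expect_equal(filterTransmission(f, 1, 700 + 4.5), 0.5, tolerance = 1e-12)
  expect_equal(filterTransmission(f, 1, 700 - 4.5), 0.5, tolerance = 1e-12)
  # bounded by the peak transmittance
  lam <- seq(350, 750, by = 2.5)
  tr <- filterTransmission(f, rep(0.3, length(lam)), lam)
  expect_true(all(tr >= 0 & tr <= f@peakTransmittance))
  expect_error(filterTransmission(f, 1.2, 550), "positionFrac")
  expect_error(filterTransmission(f, 0.5, 300), "wavelength")
})

test_that("reference spectra carry the pigment absorption features", {
  lam <- seq(400, 700, by = 0.5)
  # brown classes: deep minima at 445 and 641 nm, lesser dips 496/603
  for (cl in c("brown_a", "brown_b")) {
    r <- referenceSpectrum(cl)(lam)
    expect_true(all(r >= 0 & r <= 1))
    expect_equal(lam[which.min(r[lam >= 430 & lam <= 470]) +
                       which(lam >= 430)[1] - 1], 445, tolerance = 0.51)
    win <- lam >= 620 & lam <= 660
    expect_equal(lam[win][which.min(r[win])], 641, tolerance = 0.51)
    mins <- findAbsorptionMinima(r, list(c(480, 510), c(590, 615)), lam)
    expect_equal(unname(mins), c(496, 603), tolerance = 0.51)
  }
  # red classes: minima at 440 and 639 nm, higher reflectance in the red
  for (cl in c("red_a", "red_b")) {
    r <- referenceSpectrum(cl)
    x <- r(lam)
    win <- lam >= 425 & lam <= 465
    expect_equal(lam[win][which.min(x[win])], 440, tolerance = 0.51)
    win <- lam >= 620 & lam <= 660
    expect_equal(lam[win][which.min(x[win])], 639, tolerance = 0.51)
    expect_gt(r(660), r(550))
  }
  # lesser red-class dips distinguish the two species
  ra <- referenceSpectrum("red_a")(lam)
  rb <- referenceSpectrum("red_b")(lam)
  expect_equal(unname(findAbsorptionMinima(ra, list(c(475, 505)), lam)),
               491, tolerance = 0.51)
  expect_equal(unname(findAbsorptionMinima(rb, list(c(470, 495)), lam)),
               481, tolerance = 0.51)
  # every class peaks at the long-wavelength end
  for (cl in c("brown_a", "brown_b", "red_a", "red_b"))
    expect_equal(lam[which.max(referenceSpectrum(cl)(lam))], 700)
  # flat grey plate
  expect_equal(referenceSpectrum("grey")(lam), rep(0.1, length(lam)))
  expect_error(referenceSpectrum("kelp_z"), "unknown class")
})

test_that("scene construction is deterministic and keeps grey margins", {
  sc1 <- makeScene("four_species", rows = 48, cols = 60, marginRows = 6,
                   seed = 9)
  sc2 <- makeScene("four_species", rows = 48, cols = 60, marginRows = 6,
                   seed = 9)
  expect_identical(sc1@labelMap, sc2@labelMap)
  expect_setequal(unique(as.vector(sc1@labelMap)), 0:4)
  expect_true(all(sc1@labelMap[1:6, ] == 0))
  expect_true(all(sc1@labelMap[43:48, ] == 0))
  sc3 <- makeScene("flat_patch", rows = 48, cols = 60, flatR = 0.5)
  expect_setequal(unique(as.vector(sc3@labelMap)), 0:1)
  expect_equal(sc3@spectra$flat(c(450, 600)), c(0.5, 0.5))
  expect_error(makeScene(matrix(1L, 20, 20), classes = list(x = function(l) l * 0 + 0.3)),
               "background")
  expect_error(makeScene("no_such_layout"), "unknown layout")
})

test_that("rendering is quantized, deterministic and flat scenes are uniform", {
  scene <- makeScene("flat_patch", rows = 24, cols = 20, marginRows = 5,
                     flatR = 0.4)
  cam <- CameraSpec(rows = 24, cols = 20)
  scan <- ScanSpec(nFrames = 60, shiftSlope = 0, noiseSd = 0, seed = 2)
  stk <- renderScan(scene, cam, FilterSpec(), scan)
  expect_true(is.integer(counts(stk)))
  expect_true(all(counts(stk) >= 0 & counts(stk) <= 255))
  stk2 <- renderScan(scene, cam, FilterSpec(), scan)
  expect_identical(counts(stk), counts(stk2))
  # zero shift + flat grey rows: every column of a grey row is identical
  expect_true(all(apply(counts(stk)[30, 1:5, , ], c(1, 3),
                        function(v) length(unique(v))) == 1))
})

test_that("rendered stacks obey shear symmetry on a flat scene", {
  # counts[f, y] == counts[f + k, y - k / slope] at equal filter position
  scene <- makeScene("flat_patch", rows = 40, cols = 16, marginRows = 6,
                     flatR = 0.3)
  cam <- CameraSpec(rows = 40, cols = 16)
  stk <- renderScan(scene, cam, FilterSpec(),
                    ScanSpec(nFrames = 80, shiftSlope = 0.5, noiseSd = 0,
                             seed = 4))
  cnt <- counts(stk)
  lab <- scene@labelMap
  for (f in c(10L, 30L, 55L)) for (y in c(31L, 39L)) {
    # (f - 1) + 0.5 (y - 1) == (f) + 0.5 (y - 3): one frame later, two rows up
    same <- lab[y, ] == lab[y - 2L, ]
    expect_identical(cnt[f, y, same, ], cnt[f + 1L, y - 2L, same, ])
  }
})

test_that("doubling illumination never decreases linear-domain signal", {
  mk <- function(mult) {
    makeScene("flat_patch", rows = 24, cols = 20, marginRows = 5,
              flatR = 0.4,
              illumination = function(l) mult * rep(1, length(l)))
  }
  cam <- CameraSpec(rows = 24, cols = 20, gain = 0.5)  # fixed exposure
  scan <- ScanSpec(nFrames = 60, shiftSlope = 0.2, noiseSd = 0, seed = 2)
  lin1 <- renderScan(mk(1), cam, FilterSpec(), scan, output = "linear")
  lin2 <- renderScan(mk(2), cam, FilterSpec(), scan, output = "linear")
  expect_true(all(lin2 >= lin1))
  expect_equal(lin2, 2 * lin1, tolerance = 1e-12)
})
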
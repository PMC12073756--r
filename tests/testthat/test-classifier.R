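# 1D-CNN construction, training dynamics, prediction and metrics.

test_that("the network has the prescribed architecture and shapes", {
  m <- buildModel()
  expect_equal(m@hyper$conv1Filters, 32L)
  expect_equal(m@hyper$conv2Filters, 64L)
  expect_equal(m@hyper$kernel, 3L)
  expect_equal(m@hyper$denseUnits, 128L)
  expect_equal(m@hyper$dropout, 0.25)
  # shape propagation 45 -> 22 -> 11, 64 channels: flatten 704
  expect_equal(flattenLength(45), 704L)
  expect_equal(dim(m@params$W3), c(704L, 128L))
  expect_equal(dim(m@params$W1), c(3L, 32L))
  expect_equal(dim(m@params$W5), c(128L, 5L))
  m2 <- buildModel(nBands = 8, classLabels = c("a", "b"))
  expect_equal(flattenLength(8), 128L)
  expect_equal(dim(m2@params$W3)[1], 128L)
  expect_error(buildModel(nBands = 3), ">= 4")
})

test_that("the flatten-length formula holds across input lengths", {
  for (nb in c(4, 5, 7, 12, 29, 45, 60)) {
    m <- buildModel(nBands = nb, classLabels = c("a", "b"))
    expect_equal(dim(m@params$W3)[1],
                 64L * ((nb %/% 2L) %/% 2L))
    # the forward pass accepts this input length
    out <- scanHSI:::.cnnForward(m, matrix(0.1, 3, nb))
    expect_equal(dim(out$logits), c(3L, 2L))
  }
})

test_that("analytic gradients match numerical differentiation", {
  m <- buildModel(nBands = 8, classLabels = c("a", "b"), conv1Filters = 4,
                  conv2Filters = 6, denseUnits = 10, dropout = 0, seed = 2)
  set.seed(5)
  X <- matrix(stats::rnorm(12 * 8, 0, 0.5), 12, 8)
  y <- sample(1:2, 12, replace = TRUE)
  cache <- scanHSI:::.cnnForward(m, X, training = TRUE)
  bk <- scanHSI:::.cnnBackward(m, cache, y)
  eps <- 1e-6
  lossAt <- function(model) {
    scanHSI:::.cnnBackward(model,
                           scanHSI:::.cnnForward(model, X, training = TRUE),
                           y)$loss
  }
  for (nm in names(m@params)) {
    probe <- seq_len(min(4, length(m@params[[nm]])))
    for (j in probe) {
      mp <- m; mp@params[[nm]][j] <- m@params[[nm]][j] + eps
      mm <- m; mm@params[[nm]][j] <- m@params[[nm]][j] - eps
      num <- (lossAt(mp) - lossAt(mm)) / (2 * eps)
      expect_equal(bk$grads[[nm]][j], num, tolerance = 1e-5)
    }
  }
})

test_that("train/validation splits are stratified and deterministic", {
  lib <- tinyLibrary(n = 500)
  sp <- splitTrainVal(lib, fraction = 0.9, seed = 4)
  expect_equal(nrow(librarySpectra(sp$train)), 900)
  expect_equal(nrow(librarySpectra(sp$val)), 100)
  sp2 <- splitTrainVal(lib, fraction = 0.9, seed = 4)
  expect_identical(libraryInfo(sp$train), libraryInfo(sp2$train))
  # disjoint and exhaustive
  keyAll <- paste(libraryInfo(lib)$row, libraryInfo(lib)$col)
  keyTr <- paste(libraryInfo(sp$train)$row, libraryInfo(sp$train)$col)
  keyVa <- paste(libraryInfo(sp$val)$row, libraryInfo(sp$val)$col)
  expect_length(intersect(keyTr, keyVa), 0)
  expect_setequal(c(keyTr, keyVa), keyAll)
  # per-class proportions within one record
  for (cl in c("a", "b"))
    expect_equal(sum(libraryInfo(sp$train)$class == cl), 450)
  expect_error(splitTrainVal(lib, fraction = 1.1), "\\(0, 1\\)")
})

test_that("training separates separable classes and is reproducible", {
  lib <- tinyLibrary(n = 300)
  m <- buildModel(45, classLabels = c("a", "b"), seed = 1)
  tr <- trainModel(m, lib, epochs = 20, batchSize = 256, seed = 1)
  expect_true(tr@trained)
  expect_equal(nrow(tr@history), 20)
  # validation accuracy 1.0 on the separable problem
  sp <- splitTrainVal(lib, 0.9, seed = 1)
  pr <- predictSpectra(tr, librarySpectra(sp$val))
  expect_equal(mean(pr$class == libraryInfo(sp$val)$class), 1.0)
  # the smoothed loss trend decreases
  expect_lt(mean(tail(tr@history$trainLoss, 5)),
            mean(head(tr@history$trainLoss, 5)))
  # same seeds, same final weights
  tr2 <- trainModel(buildModel(45, classLabels = c("a", "b"), seed = 1),
                    lib, epochs = 20, batchSize = 256, seed = 1)
  expect_identical(tr@params, tr2@params)
  expect_identical(tr@history, tr2@history)
  # every model class must be represented
  m3 <- buildModel(45, classLabels = c("a", "b", "c"), seed = 1)
  expect_error(trainModel(m3, lib, epochs = 1), "no training records")
})

test_that("cube prediction labels valid pixels and reports coverage", {
  lib <- tinyLibrary(n = 300)
  tr <- trainModel(buildModel(45, classLabels = c("a", "b"), seed = 1),
                   lib, epochs = 15, batchSize = 256, seed = 1)
  # cube of pure class-a spectra plus a masked pixel
  set.seed(9)
  vals <- array(stats::rnorm(6 * 5 * 45, 0.2, 0.02), dim = c(6, 5, 45))
  cube <- syntheticCube(vals, bandCenters = bandCenters(lib))
  cube@validMask[1, 1, 3] <- FALSE
  pred <- predictCube(tr, cube)
  expect_equal(pred$labels[1, 1], "unknown")
  expect_equal(pred$nValid, 29)
  expect_true(all(pred$labels[-1, ] == "a"))
  expect_equal(sum(pred$coverage), 1.0)
  expect_gte(pred$coverage["a"], 0.99)
  wrong <- syntheticCube(array(0.2, dim = c(2, 2, 10)))
  expect_error(predictCube(tr, wrong), "expects")
})

test_that("segmentation metrics follow the precision/recall/F1 identities", {
  # perfect prediction
  pred <- matrix("a", 6, 6)
  ann <- annotationTable("c", "a", 0, 0, 6, 6)
  perfect <- evaluateSegmentation(pred, ann)
  expect_equal(unname(macroMetrics(perfect)), c(1, 1, 1))
  # the worked confusion: TP = 9, FP = 1, FN = 3
  pred2 <- matrix("bg", 4, 4)
  pred2[1:3, 1:3] <- "a"     # 9 true positives (truth-a is rows 1-3)
  pred2[4, 1] <- "a"         # 1 false positive on the background row
  truthBoxes <- rbind(annotationTable("c", "a", 0, 0, 4, 3),
                      annotationTable("c", "bg", 0, 3, 4, 4))
  m2 <- evaluateSegmentation(pred2, truthBoxes, backgroundClass = "bg")
  tab <- metricsTable(m2)
  arow <- tab[tab$class == "a", ]
  expect_equal(arow$precision, 0.9)
  expect_equal(arow$recall, 0.75)
  expect_equal(arow$f1, 2 * 0.9 * 0.75 / (0.9 + 0.75))
  # F1 lies between precision and recall; macro equals the mean
  expect_gte(arow$f1, min(arow$precision, arow$recall))
  expect_lte(arow$f1, max(arow$precision, arow$recall))
  # class absent from the truth reports NA
  pred3 <- matrix("a", 3, 3)
  ann3 <- rbind(annotationTable("c", "a", 0, 0, 3, 3),
                annotationTable("c", "ghost", 0, 0, 1, 1))
  expect_error(evaluateSegmentation(pred3, ann3), "conflicting")
  ann4 <- annotationTable("c", "a", 0, 0, 3, 3)
  m4 <- evaluateSegmentation(pred3, ann4)
  expect_false("ghost" %in% metricsTable(m4)$class)
})
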
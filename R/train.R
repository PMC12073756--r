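# Training, prediction and model persistence for the 1D-CNN.

#' @include AllClasses.R specs.R cnn.R library.R
NULL

# Subset a library by record indices.
.subsetLibrary <- function(library, idx) {
  new("SpectralLibrary", spectra = library@spectra[idx, , drop = FALSE],
      info = library@info[idx, , drop = FALSE],
      bandCenters = library@bandCenters)
}

#' Stratified train/validation split
#'
#' Splits the library into disjoint, exhaustive train and validation sets,
#' stratified by class (per-class proportions preserved within one record)
#' and deterministic for a fixed seed.
#'
#' @param library a [SpectralLibrary-class] with >= 10 records.
#' @param fraction training fraction (default 0.9).
#' @param seed RNG seed.
#' @return list with [SpectralLibrary-class] elements `train` and `val`.
#' @export
splitTrainVal <- function(library, fraction = 0.9, seed = 1L) {
  stopifnot(is(library, "SpectralLibrary"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- nrow(library@spectra)
  if (n < 10) stop("need >= 10 records to split")
  trainIdx <- .withSeed(seed, {
    unlist(lapply(split(seq_len(n), library@info$class), function(idx) {
      k <- round(fraction * length(idx))
      sample(idx, k)
    }), use.names = FALSE)
  })
  list(train = .subsetLibrary(library, sort(trainIdx)),
       val = .subsetLibrary(library, sort(setdiff(seq_len(n), trainIdx))))
}

#' Train the 1D-CNN on a spectral library
#'
#' Minimizes cross-entropy with Adam over shuffled mini-batches, with all
#' classes weighted equally, and records per-epoch training and validation
#' losses (the surface used to monitor overfitting and choose the epoch
#' budget). Training is deterministic for fixed seeds: weight
#' initialization comes from [buildModel()]'s seed, while shuffling and
#' dropout draw from `seed`.
#'
#' @param model an untrained (or pre-trained) [ConvNet1D-class].
#' @param library the training [SpectralLibrary-class]; its classes must be
#'   a subset of the model's, and every model class must be represented.
#' @param epochs training epochs (default 300).
#' @param batchSize mini-batch size (default 256).
#' @param valFraction validation share carved out by [splitTrainVal()]
#'   (default 0.1, i.e. a 90/10 split).
#' @param lr Adam learning rate.
#' @param seed seed for shuffling and dropout.
#' @param verbose print the loss every 10 epochs.
#' @return The trained [ConvNet1D-class] (see its `history` slot).
#' @export
trainModel <- function(model, library, epochs = 300, batchSize = 256,
                       valFraction = 0.1, lr = 1e-3, seed = 1L,
                       verbose = FALSE) {
  stopifnot(is(model, "ConvNet1D"), is(library, "SpectralLibrary"))
  if (ncol(library@spectra) != model@nBands)
    stop("library band count (", ncol(library@spectra),
         ") does not match the model input length (", model@nBands, ")")
  libClasses <- unique(library@info$class)
  extra <- setdiff(libClasses, model@classLabels)
  if (length(extra))
    stop("library contains classes unknown to the model: ",
         paste(extra, collapse = ", "))
  empty <- setdiff(model@classLabels, libClasses)
  if (length(empty))
    stop("no training records for class(es): ",
         paste(empty, collapse = ", "))
  parts <- splitTrainVal(library, 1 - valFraction, seed)
  Xtr <- parts$train@spectra
  ytr <- match(parts$train@info$class, model@classLabels)
  Xva <- parts$val@spectra
  yva <- match(parts$val@info$class, model@classLabels)
  nTr <- nrow(Xtr)
  params <- model@params
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  hist <- data.frame(epoch = seq_len(epochs), trainLoss = NA_real_,
                     valLoss = NA_real_)
  .withSeed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nTr)
      starts <- seq(1L, nTr, by = batchSize)
      lossSum <- 0; nSeen <- 0L
      for (s in starts) {
        idx <- ord[s:min(s + batchSize - 1L, nTr)]
        model@params <- params
        cache <- .cnnForward(model, Xtr[idx, , drop = FALSE],
                             training = TRUE)
        bk <- .cnnBackward(model, cache, ytr[idx])
        upd <- .adamStep(params, bk$grads, state, lr = lr)
        params <- upd$params; state <- upd$state
        lossSum <- lossSum + bk$loss * length(idx)
        nSeen <- nSeen + length(idx)
      }
      model@params <- params
      val <- .cnnForward(model, Xva, training = FALSE, wantCache = TRUE)
      vl <- .cnnBackward(model, val, yva)$loss
      hist$trainLoss[ep] <- lossSum / nSeen
      hist$valLoss[ep] <- vl
      if (verbose && (ep %% 10 == 0 || ep == 1))
        message(sprintf("epoch %3d  train %.4f  val %.4f", ep,
                        hist$trainLoss[ep], vl))
    }
  })
  model@params <- params
  model@trained <- TRUE
  model@history <- rbind(model@history, hist)
  model
}

#' Classify per-pixel spectra
#'
#' @param model a trained [ConvNet1D-class].
#' @param spectra matrix, one spectrum per row (`nBands` columns).
#' @param chunk rows evaluated per forward pass.
#' @return list with `class` (character vector) and `prob` (softmax
#'   matrix, one column per model class).
#' @export
predictSpectra <- function(model, spectra, chunk = 8192L) {
  stopifnot(is(model, "ConvNet1D"))
  if (ncol(spectra) != model@nBands)
    stop("spectra have ", ncol(spectra), " bands; the model expects ",
         model@nBands)
  n <- nrow(spectra)
  prob <- matrix(0, n, model@nClasses,
                 dimnames = list(NULL, model@classLabels))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    fw <- .cnnForward(model, spectra[idx, , drop = FALSE],
                      training = FALSE)
    prob[idx, ] <- .softmax(fw$logits)
  }
  cls <- model@classLabels[max.col(prob, ties.method = "first")]
  list(class = cls, prob = prob)
}

#' Segment a hypercube pixel by pixel
#'
#' Runs the classifier over every valid pixel of a cube (argmax class) and
#' reports per-class coverage fractions over the valid pixels. A pixel is
#' invalid -- labeled `"unknown"` -- when it is masked in any band that the
#' cube as a whole covers (bands invalid for every pixel carry no
#' information and are ignored).
#'
#' @param model a trained [ConvNet1D-class].
#' @param cube a reflectance [Hypercube-class] with `nBands(model)` bands.
#' @return list with `labels` (character row x col matrix), `coverage`
#'   (named fractions over valid pixels, summing to 1) and `nValid`.
#' @export
predictCube <- function(model, cube) {
  stopifnot(is(model, "ConvNet1D"), is(cube, "Hypercube"))
  if (nBands(cube) != model@nBands)
    stop("cube has ", nBands(cube), " bands; the model expects ",
         model@nBands)
  d <- dim(cube@values)
  npix <- d[1] * d[2]
  V <- matrix(cube@values, npix, d[3])
  M <- matrix(cube@validMask, npix, d[3])
  gib <- .globallyInvalidBands(cube)
  validPix <- rowSums(!M[, !gib, drop = FALSE]) == 0
  labels <- matrix("unknown", d[1], d[2])
  if (any(validPix)) {
    pred <- predictSpectra(model, V[validPix, , drop = FALSE])
    labels[validPix] <- pred$class
  }
  cov <- table(factor(labels[validPix], levels = model@classLabels))
  coverage <- as.numeric(cov) / max(sum(validPix), 1L)
  names(coverage) <- model@classLabels
  list(labels = labels, coverage = coverage, nValid = sum(validPix))
}

#' Save or load a model checkpoint
#'
#' Writes the weights as a flat little-endian double vector
#' (`<path>.bin`) with a JSON sidecar (`<path>.json`) describing shapes,
#' hyperparameters, class labels and training history.
#'
#' @param model a [ConvNet1D-class].
#' @param path checkpoint path prefix (no extension).
#' @return `saveModel()` the prefix, invisibly; `loadModel()` the restored
#'   [ConvNet1D-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "ConvNet1D"))
  shapes <- lapply(model@params, function(p)
    if (is.matrix(p)) dim(p) else length(p))
  side <- list(nBands = model@nBands, nClasses = model@nClasses,
               classLabels = model@classLabels, hyper = model@hyper,
               trained = model@trained, shapes = shapes,
               history = model@history)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (p in model@params)
    writeBin(as.vector(p), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  jsonPath <- paste0(path, ".json"); binPath <- paste0(path, ".bin")
  if (!file.exists(jsonPath) || !file.exists(binPath))
    stop("model checkpoint not found at prefix: ", path)
  side <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  con <- file(binPath, "rb")
  on.exit(close(con))
  params <- list()
  for (nm in names(side$shapes)) {
    sh <- unlist(side$shapes[[nm]])
    n <- prod(sh)
    v <- readBin(con, "double", n = n, size = 8, endian = "little")
    params[[nm]] <- if (length(sh) == 2) matrix(v, sh[1], sh[2]) else v
  }
  hist <- as.data.frame(side$history)
  if (!nrow(hist)) hist <- data.frame(epoch = integer(),
                                      trainLoss = numeric(),
                                      valLoss = numeric())
  new("ConvNet1D", nBands = as.integer(side$nBands),
      nClasses = as.integer(side$nClasses),
      classLabels = side$classLabels,
      hyper = lapply(side$hyper, function(x)
        if (is.numeric(x) && x == round(x) && !identical(x, side$hyper$dropout))
          as.integer(x) else x),
      params = params, trained = isTRUE(side$trained), history = hist)
}
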
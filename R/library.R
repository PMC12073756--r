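# Annotations, labeled-pixel extraction, class mean spectra and
# absorption-feature localization.

#' @include AllClasses.R specs.R
NULL

# Bands that are invalid for *every* pixel of a cube (outside the scan's
# wavelength coverage); these carry no information and do not disqualify
# pixels.
.globallyInvalidBands <- function(cube) {
  d <- dim(cube@validMask)
  colSums(matrix(cube@validMask, d[1] * d[2], d[3])) == 0
}

#' Create an annotation table
#'
#' Pixel-box annotations use 0-based, half-open boxes in image coordinates:
#' a box `(colMin, rowMin, colMax, rowMax)` covers columns
#' `colMin .. colMax - 1` and rows `rowMin .. rowMax - 1` (0-based), i.e.
#' `(colMax - colMin) * (rowMax - rowMin)` pixels.
#'
#' @param cubeId cube identifier(s).
#' @param class class label(s).
#' @param colMin,rowMin,colMax,rowMax box coordinates (0-based, half-open).
#' @return data.frame with one row per box.
#' @export
annotationTable <- function(cubeId, class, colMin, rowMin, colMax, rowMax) {
  df <- data.frame(cubeId = cubeId, class = class,
                   colMin = as.integer(colMin), rowMin = as.integer(rowMin),
                   colMax = as.integer(colMax), rowMax = as.integer(rowMax),
                   stringsAsFactors = FALSE)
  if (any(df$colMax <= df$colMin) || any(df$rowMax <= df$rowMin))
    stop("annotation boxes must be non-empty (half-open: max > min)")
  df
}

#' Read or write annotations as JSON lines
#'
#' One JSON object per line with fields `cubeId`, `class`, `colMin`,
#' `rowMin`, `colMax`, `rowMax` (0-based, half-open boxes).
#'
#' @param path file path.
#' @param annotations data.frame from [annotationTable()].
#' @return `readAnnotations()` returns the data.frame; `writeAnnotations()`
#'   the path, invisibly.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("annotation file is empty: ", path)
  rows <- lapply(lines, jsonlite::fromJSON)
  do.call(rbind, lapply(rows, function(r)
    annotationTable(r$cubeId, r$class, r$colMin, r$rowMin, r$colMax,
                    r$rowMax)))
}

#' @rdname readAnnotations
#' @export
writeAnnotations <- function(annotations, path) {
  lines <- vapply(seq_len(nrow(annotations)), function(i)
    as.character(jsonlite::toJSON(as.list(annotations[i, ]),
                                  auto_unbox = TRUE)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Derive annotations from a scene's ground truth
#'
#' Builds one inset bounding box per class from a simulated scene's label
#' map (the class patches are rectangular), plus optional background boxes
#' over the grey margins. Mirrors how real cubes are annotated from their
#' RGB images, but with the simulator's exact truth.
#'
#' @param scene a [SceneSpec-class].
#' @param cubeId cube identifier the boxes refer to.
#' @param inset pixels shaved off each box edge (keeps annotations inside
#'   the patch, as a human annotator would).
#' @param background also annotate the grey margins as class `"grey"`.
#' @return Annotation data.frame (see [annotationTable()]).
#' @export
annotationsFromScene <- function(scene, cubeId, inset = 2,
                                 background = TRUE) {
  stopifnot(is(scene, "SceneSpec"))
  lm <- scene@labelMap
  out <- list()
  for (k in seq_along(scene@classNames)) {
    idx <- which(lm == k, arr.ind = TRUE)
    if (!nrow(idx)) next
    r <- range(idx[, 1]); cl <- range(idx[, 2])
    out[[length(out) + 1L]] <- annotationTable(
      cubeId, scene@classNames[k],
      colMin = cl[1] - 1L + inset, rowMin = r[1] - 1L + inset,
      colMax = cl[2] - inset, rowMax = r[2] - inset)
  }
  if (background) {
    m <- scene@marginRows
    nR <- nrow(lm); nC <- ncol(lm)
    out[[length(out) + 1L]] <- annotationTable(
      cubeId, "grey", colMin = inset, rowMin = inset,
      colMax = nC - inset, rowMax = m - inset)
    out[[length(out) + 1L]] <- annotationTable(
      cubeId, "grey", colMin = inset, rowMin = nR - m + inset,
      colMax = nC - inset, rowMax = nR - inset)
  }
  do.call(rbind, out)
}

#' Extract labeled per-pixel spectra from annotated cubes
#'
#' Collects one record per pixel inside each annotation box. Pixels that are
#' masked in any band the cube covers (beyond the bands invalid for every
#' pixel, which carry no information) are dropped; overlapping boxes of the
#' same class are merged (set union), and conflicting labels on one pixel
#' are an error.
#'
#' @param cubes a [Hypercube-class] or named list of them (names are cube
#'   ids).
#' @param annotations data.frame from [annotationTable()] /
#'   [readAnnotations()].
#' @param verbose print per-class record counts.
#' @return A [SpectralLibrary-class].
#' @export
extractLabeledPixels <- function(cubes, annotations, verbose = FALSE) {
  if (is(cubes, "Hypercube")) {
    nm <- unique(annotations$cubeId)
    if (length(nm) != 1)
      stop("a single cube was given but annotations reference several cube ids")
    cubes <- stats::setNames(list(cubes), nm)
  }
  bc <- bandCenters(cubes[[1]])
  recs <- list()
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    cube <- cubes[[a$cubeId]]
    if (is.null(cube))
      stop("annotation ", i, " references unknown cube '", a$cubeId, "'")
    d <- dim(cube@values)
    rows <- (a$rowMin + 1L):a$rowMax
    cols <- (a$colMin + 1L):a$colMax
    if (a$rowMin < 0 || a$colMin < 0 || a$rowMax > d[1] || a$colMax > d[2])
      stop("annotation ", i, " (cube '", a$cubeId, "', class '", a$class,
           "') is out of bounds")
    recs[[i]] <- data.frame(cubeId = a$cubeId,
                            row = rep(rows, times = length(cols)),
                            col = rep(cols, each = length(rows)),
                            class = a$class, stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, recs)
  key <- paste(recs$cubeId, recs$row, recs$col)
  if (anyDuplicated(key)) {
    cls <- tapply(recs$class, key, function(x) length(unique(x)))
    if (any(cls > 1))
      stop("overlapping annotations assign conflicting classes to a pixel")
    recs <- recs[!duplicated(key), ]
  }
  spectra <- matrix(0, nrow(recs), length(bc))
  keep <- logical(nrow(recs))
  for (id in unique(recs$cubeId)) {
    cube <- cubes[[id]]
    d <- dim(cube@values)
    gib <- .globallyInvalidBands(cube)
    sel <- recs$cubeId == id
    pix <- recs$row[sel] + (recs$col[sel] - 1L) * d[1]
    V <- matrix(cube@values, d[1] * d[2], d[3])
    M <- matrix(cube@validMask, d[1] * d[2], d[3])
    spectra[sel, ] <- V[pix, , drop = FALSE]
    keep[sel] <- rowSums(!M[pix, !gib, drop = FALSE]) == 0
  }
  dropped <- sum(!keep)
  if (dropped > 0)
    warning(dropped, " pixel(s) dropped: masked in a covered band")
  if (!any(keep)) warning("all annotated pixels were masked")
  recs <- recs[keep, , drop = FALSE]
  spectra <- spectra[keep, , drop = FALSE]
  if (verbose && nrow(recs)) {
    tab <- table(recs$class)
    message("extracted records per class: ",
            paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  rownames(recs) <- NULL
  new("SpectralLibrary", spectra = spectra, info = recs, bandCenters = bc)
}

#' Per-class mean and standard deviation spectra
#'
#' @param library a [SpectralLibrary-class].
#' @param classes classes to summarize (default: all present).
#' @return list with matrices `mean` and `sd` (class x band) and the
#'   `bandCenters`.
#' @export
classMeanSpectra <- function(library, classes = NULL) {
  stopifnot(is(library, "SpectralLibrary"))
  if (is.null(classes)) classes <- classLabels(library)
  missing <- setdiff(classes, library@info$class)
  if (length(missing))
    stop("no records for class(es): ", paste(missing, collapse = ", "))
  B <- ncol(library@spectra)
  mn <- sd <- matrix(0, length(classes), B,
                     dimnames = list(classes, NULL))
  for (cl in classes) {
    X <- library@spectra[library@info$class == cl, , drop = FALSE]
    mn[cl, ] <- colMeans(X)
    sd[cl, ] <- if (nrow(X) > 1) apply(X, 2, stats::sd) else 0
  }
  list(mean = mn, sd = sd, bandCenters = library@bandCenters)
}

#' Locate absorption minima in a spectrum
#'
#' Finds local reflectance minima (strictly smaller than both neighbors)
#' within each search window; per window the deepest minimum is returned,
#' ties broken toward the shorter wavelength. Windows without a local
#' minimum yield `NA`.
#'
#' @param spectrum reflectance values.
#' @param searchWindows list of `c(min, max)` nm windows (optionally
#'   named).
#' @param bandCenters wavelengths (nm) of `spectrum`.
#' @return Named numeric vector of minima wavelengths (one per window).
#' @examples
#' lam <- seq(400, 700, by = 1)
#' findAbsorptionMinima(referenceSpectrum("brown_a")(lam),
#'                      list(c(430, 470)), lam)
#' @export
findAbsorptionMinima <- function(spectrum, searchWindows, bandCenters) {
  if (length(spectrum) < 3) stop("spectrum must have >= 3 points")
  if (length(bandCenters) != length(spectrum))
    stop("bandCenters must match the spectrum length")
  n <- length(spectrum)
  isMin <- c(FALSE, spectrum[2:(n - 1)] < spectrum[1:(n - 2)] &
               spectrum[2:(n - 1)] < spectrum[3:n], FALSE)
  out <- vapply(searchWindows, function(w) {
    cand <- which(isMin & bandCenters >= w[1] & bandCenters <= w[2])
    if (!length(cand)) return(NA_real_)
    best <- cand[order(spectrum[cand], bandCenters[cand])][1]
    bandCenters[best]
  }, numeric(1))
  if (is.null(names(searchWindows)))
    names(out) <- vapply(searchWindows,
                         function(w) paste0(w[1], "-", w[2], "nm"),
                         character(1))
  out
}
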
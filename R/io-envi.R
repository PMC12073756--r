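# ENVI reader/writer: text header + band-sequential float32 little-endian
# data, with a companion byte mask.

#' @include AllClasses.R specs.R
NULL

#' Write a hypercube as an ENVI image
#'
#' Produces `<path>.hdr` (text header with the wavelength list),
#' `<path>.dat` (band-sequential 32-bit float, little-endian) and
#' `<path>.msk` (validity mask, one byte per entry, same BSQ layout).
#'
#' @param cube a [Hypercube-class].
#' @param path output path prefix (no extension).
#' @return The prefix, invisibly.
#' @export
writeENVI <- function(cube, path) {
  stopifnot(is(cube, "Hypercube"))
  d <- dim(cube@values)
  hdr <- c(
    "ENVI",
    "description = {scanHSI reflectance hypercube}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {",
           paste(format(cube@bandCenters, trim = TRUE, digits = 10),
                 collapse = ", "), "}"),
    paste0("mask file = ", basename(paste0(path, ".msk")))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  # BSQ: sample (col) fastest, then line (row), then band
  bsq <- aperm(cube@values, c(2, 1, 3))
  con <- file(paste0(path, ".dat"), "wb")
  writeBin(as.vector(bsq), con, size = 4, endian = "little")
  close(con)
  msk <- aperm(cube@validMask, c(2, 1, 3))
  con <- file(paste0(path, ".msk"), "wb")
  writeBin(as.integer(msk), con, size = 1)
  close(con)
  invisible(path)
}

# Parse an ENVI header into a named list (multi-line {...} values joined).
.parseEnviHeader <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || toupper(trimws(lines[1])) != "ENVI")
    stop("not an ENVI header (missing ENVI magic line): ", path)
  txt <- paste(lines[-1], collapse = "\n")
  # join braces spanning lines, then split on newlines outside braces
  fields <- list()
  pos <- 1L
  pat <- gregexpr("([a-zA-Z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)", txt,
                  perl = TRUE)[[1]]
  if (pat[1] == -1) stop("malformed ENVI header: ", path)
  starts <- as.vector(pat); lens <- attr(pat, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    eq <- regexpr("=", piece, fixed = TRUE)
    key <- tolower(trimws(substr(piece, 1, eq - 1)))
    val <- trimws(substr(piece, eq + 1, nchar(piece)))
    fields[[key]] <- val
  }
  fields
}

.enviNum <- function(fields, key) {
  v <- fields[[key]]
  if (is.null(v)) stop("ENVI header is missing required field '", key, "'")
  n <- suppressWarnings(as.numeric(v))
  if (is.na(n)) stop("ENVI header field '", key, "' is not numeric")
  n
}

#' Read an ENVI hypercube
#'
#' Reads the `<path>.hdr` / `<path>.dat` pair written by [writeENVI()]
#' (BSQ, data type 4 = float32, byte order 0) and the companion mask if
#' present. Header/data consistency is validated: dimensions, data type,
#' interleave, wavelength-list length and file size must agree.
#'
#' @param path path prefix (no extension).
#' @return A [Hypercube-class] (`scene = NULL`).
#' @export
readENVI <- function(path) {
  hdrPath <- paste0(path, ".hdr"); datPath <- paste0(path, ".dat")
  if (!file.exists(hdrPath)) stop("ENVI header not found: ", hdrPath)
  if (!file.exists(datPath)) stop("ENVI data file not found: ", datPath)
  f <- .parseEnviHeader(hdrPath)
  samples <- .enviNum(f, "samples"); lines <- .enviNum(f, "lines")
  bands <- .enviNum(f, "bands")
  if (.enviNum(f, "data type") != 4)
    stop("unsupported ENVI data type (expected 4 = float32)")
  if (!is.null(f[["interleave"]]) && tolower(f[["interleave"]]) != "bsq")
    stop("unsupported ENVI interleave (expected bsq)")
  wl <- f[["wavelength"]]
  if (is.null(wl)) stop("ENVI header is missing the wavelength list")
  wl <- as.numeric(strsplit(gsub("[{}]", "", wl), ",")[[1]])
  if (anyNA(wl) || length(wl) != bands)
    stop("ENVI wavelength list length does not match the band count")
  nVal <- samples * lines * bands
  if (file.size(datPath) != 4 * nVal)
    stop("ENVI data file size does not match the header dimensions")
  con <- file(datPath, "rb")
  v <- readBin(con, "double", n = nVal, size = 4, endian = "little")
  close(con)
  vals <- aperm(array(v, c(samples, lines, bands)), c(2, 1, 3))
  mskPath <- paste0(path, ".msk")
  valid <- if (file.exists(mskPath)) {
    con <- file(mskPath, "rb")
    m <- readBin(con, "integer", n = nVal, size = 1, signed = FALSE)
    close(con)
    if (length(m) != nVal)
      stop("ENVI mask file size does not match the header dimensions")
    aperm(array(m > 0, c(samples, lines, bands)), c(2, 1, 3))
  } else array(TRUE, dim(vals))
  new("Hypercube", values = vals, bandCenters = wl, validMask = valid,
      scene = NULL, processing = list(source = paste0(path, ".dat")))
}
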
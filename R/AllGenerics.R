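#' @include AllClasses.R
NULL

#' Accessors for scanHSI objects
#'
#' Small family of read-only accessors used across the package instead of
#' direct slot access: `counts()` returns the raw integer frame stack of a
#' [RawScanStack-class], `cubeValues()` / `bandCenters()` / `validMask()`
#' expose the contents of a [Hypercube-class], `nBands()` the spectral
#' dimension of a cube, library or model, `classLabels()` the class
#' vocabulary of a [SpectralLibrary-class] or [ConvNet1D-class], and
#' `shiftSlope()` the frames-per-row slope of a [ShiftModel-class].
#'
#' @param x an object of the documented class.
#' @return The slot value; see the class documentation for details.
#' @name accessors
#' @aliases counts cubeValues bandCenters validMask nBands classLabels
#'   shiftSlope
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("cubeValues", function(x) standardGeneric("cubeValues"))

#' @rdname accessors
#' @export
setGeneric("bandCenters", function(x) standardGeneric("bandCenters"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("shiftSlope", function(x) standardGeneric("shiftSlope"))
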
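# Segmentation evaluation: per-class precision/recall/F1 over annotated
# pixels and the macro average over the species classes.

#' @include AllClasses.R specs.R library.R
NULL

#' Evaluate a segmentation against annotations
#'
#' Scores a predicted label map on the annotated pixels only: per class,
#' precision `TP / (TP + FP)`, recall `TP / (TP + FN)` and their harmonic
#' mean F1. The macro average is the unweighted mean across the foreground
#' (species) classes; the background class participates in the per-class
#' table but not in the macro average. Classes absent from the ground truth
#' are reported as `NA`. Pixels predicted `"unknown"` count against recall
#' of their true class.
#'
#' @param pred predicted labels: a character (row x col) matrix or the list
#'   returned by [predictCube()].
#' @param annotations ground-truth boxes (see [annotationTable()]) for this
#'   cube.
#' @param cubeId restrict annotations to this cube id (default: all rows).
#' @param backgroundClass label excluded from the macro average.
#' @return A [ClassMetrics-class].
#' @examples
#' pred <- matrix("a", 4, 4)
#' ann <- annotationTable("c1", "a", 0, 0, 4, 4)
#' evaluateSegmentation(pred, ann)
#' @export
evaluateSegmentation <- function(pred, annotations, cubeId = NULL,
                                 backgroundClass = "grey") {
  if (is.list(pred) && !is.null(pred$labels)) pred <- pred$labels
  if (!is.matrix(pred)) stop("pred must be a label matrix or predictCube() output")
  if (!is.null(cubeId))
    annotations <- annotations[annotations$cubeId == cubeId, , drop = FALSE]
  if (!nrow(annotations)) stop("no annotations for the evaluated cube")
  truth <- matrix(NA_character_, nrow(pred), ncol(pred))
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    if (a$rowMax > nrow(pred) || a$colMax > ncol(pred) ||
        a$rowMin < 0 || a$colMin < 0)
      stop("annotation ", i, " is out of bounds for the label map")
    rows <- (a$rowMin + 1L):a$rowMax
    cols <- (a$colMin + 1L):a$colMax
    cur <- truth[rows, cols]
    if (any(!is.na(cur) & cur != a$class))
      stop("overlapping annotations assign conflicting classes")
    truth[rows, cols] <- a$class
  }
  sel <- !is.na(truth)
  t <- truth[sel]; p <- pred[sel]
  classes <- sort(unique(c(t, setdiff(unique(annotations$class), t))))
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(p == cl & t == cl)
    fp <- sum(p == cl & t != cl)
    fn <- sum(p != cl & t == cl)
    support <- sum(t == cl)
    if (support == 0)
      return(data.frame(class = cl, precision = NA_real_,
                        recall = NA_real_, f1 = NA_real_, support = 0L))
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- tp / (tp + fn)
    f1 <- if (!is.na(prec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else
        if (!is.na(prec)) 0 else NA_real_
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = support)
  }))
  fg <- per[per$class != backgroundClass, , drop = FALSE]
  macro <- c(precision = mean(fg$precision, na.rm = TRUE),
             recall = mean(fg$recall, na.rm = TRUE),
             f1 = mean(fg$f1, na.rm = TRUE))
  new("ClassMetrics", perClass = per, macro = macro)
}

#' Per-class and macro metrics as plain values
#'
#' @param x a [ClassMetrics-class].
#' @return `metricsTable()` the per-class data.frame; `macroMetrics()` the
#'   named macro vector.
#' @export
metricsTable <- function(x) {
  stopifnot(is(x, "ClassMetrics"))
  x@perClass
}

#' @rdname metricsTable
#' @export
macroMetrics <- function(x) {
  stopifnot(is(x, "ClassMetrics"))
  x@macro
}
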
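#' @import methods
NULL

## Canonical class order used everywhere a binary score vector appears.
BINARY_LEVELS <- c("no_ok", "ok")
GROUP_LEVELS <- 1:4

#' Fuzzy membership function
#'
#' A piecewise-linear fuzzy set over \eqn{[0,1]}: triangular (3 breakpoints)
#' or trapezoidal (4 breakpoints). Membership is 1 on the peak/plateau,
#' linear on the shoulders and 0 outside the support. Breakpoints equal to
#' the domain ends produce shoulder sets (membership 1 up to/from the edge).
#'
#' @slot kind either \code{"triangular"} or \code{"trapezoidal"}.
#' @slot breakpoints non-decreasing numeric vector in \eqn{[0,1]},
#'   length 3 (triangular) or 4 (trapezoidal).
#' @export
setClass("MembershipFunction",
  representation(kind = "character", breakpoints = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("triangular", "trapezoidal"))
      return("kind must be 'triangular' or 'trapezoidal'")
    n <- if (object@kind == "triangular") 3L else 4L
    bp <- object@breakpoints
    if (length(bp) != n)
      return(sprintf("%s membership function needs %d breakpoints", object@kind, n))
    if (any(is.na(bp)) || any(bp < 0) || any(bp > 1))
      return("breakpoints must lie in [0,1]")
    if (is.unsorted(bp)) return("breakpoints must be non-decreasing")
    TRUE
  })

#' Mamdani fuzzy inference system specification
#'
#' Declares the fuzzy sets over the three model-score inputs, the output
#' sets, and the rule base. Inference is fixed to the Mamdani scheme the
#' voting step uses: minimum AND, minimum implication, maximum aggregation
#' and centroid defuzzification on a uniform grid.
#'
#' @slot inputSets named list of \linkS4class{MembershipFunction}, shared by
#'   the three inputs.
#' @slot outputSets named list of \linkS4class{MembershipFunction}.
#' @slot rules data.frame with columns \code{in1,in2,in3} (input set names)
#'   and \code{out} (output set name), one row per rule.
#' @export
setClass("FisSpec",
  representation(inputSets = "list", outputSets = "list", rules = "data.frame"),
  validity = function(object) {
    if (is.null(names(object@inputSets)) || any(names(object@inputSets) == ""))
      return("inputSets must be a named list")
    if (is.null(names(object@outputSets)) || any(names(object@outputSets) == ""))
      return("outputSets must be a named list")
    isMf <- function(x) is(x, "MembershipFunction")
    if (!all(vapply(object@inputSets, isMf, logical(1))))
      return("every input set must be a MembershipFunction")
    if (!all(vapply(object@outputSets, isMf, logical(1))))
      return("every output set must be a MembershipFunction")
    r <- object@rules
    need <- c("in1", "in2", "in3", "out")
    if (!all(need %in% names(r)))
      return("rules must have columns in1, in2, in3, out")
    if (nrow(r) == 0L) return("rule base is empty")
    ante <- unlist(r[, c("in1", "in2", "in3")], use.names = FALSE)
    if (!all(ante %in% names(object@inputSets)))
      return(sprintf("rule references undeclared input set(s): %s",
                     paste(setdiff(ante, names(object@inputSets)), collapse = ", ")))
    if (!all(r$out %in% names(object@outputSets)))
      return(sprintf("rule references undeclared output set(s): %s",
                     paste(setdiff(r$out, names(object@outputSets)), collapse = ", ")))
    TRUE
  })

#' HFUS frame collection with expert annotations
#'
#' The central data container: per-frame identifiers parsed from the file
#' names, the three expert labels, and (optionally) the pixel arrays.
#'
#' @slot frameInfo data.frame with columns \code{file_name}, \code{patient_id},
#'   \code{facial_location}, \code{image_id}, \code{session_id} and, for
#'   synthetic data, \code{true_quality} and \code{true_class}.
#' @slot annotations character matrix (n x 3, values \code{"ok"}/\code{"no_ok"}),
#'   columns Expert1..Expert3.
#' @slot pixels list of length n; each element either an integer array
#'   224 x 224 x 3 with values in [0, 255], or NULL when pixels were not loaded.
#' @export
setClass("HfusDataset",
  representation(frameInfo = "data.frame", annotations = "matrix", pixels = "list"),
  validity = function(object) {
    n <- nrow(object@frameInfo)
    need <- c("file_name", "patient_id", "facial_location", "image_id", "session_id")
    if (!all(need %in% names(object@frameInfo)))
      return(paste("frameInfo lacks columns:",
                   paste(setdiff(need, names(object@frameInfo)), collapse = ", ")))
    if (nrow(object@annotations) != n)
      return("annotations and frameInfo disagree on the number of frames")
    if (ncol(object@annotations) != 3L)
      return("annotations must have exactly 3 expert columns")
    if (!all(object@annotations %in% BINARY_LEVELS))
      return("annotations must be 'ok' or 'no_ok'")
    if (length(object@pixels) != n)
      return("pixels list length must equal the number of frames")
    keys <- do.call(paste, c(object@frameInfo[c("session_id", "patient_id",
                                                "facial_location", "image_id")],
                             sep = "\r"))
    if (anyDuplicated(keys))
      return("(session_id, patient_id, facial_location, image_id) must be unique")
    loaded <- !vapply(object@pixels, is.null, logical(1))
    for (i in which(loaded)) {
      d <- dim(object@pixels[[i]])
      if (!identical(d, c(224L, 224L, 3L)))
        return(sprintf("frame %d pixels are not 224 x 224 x 3", i))
    }
    TRUE
  })

#' Result of one processing path
#'
#' @slot pathId integer in 1..8.
#' @slot predictions per-frame predicted label: character (\code{"ok"}/
#'   \code{"no_ok"}) for the binary paths 1-4, integer group 1-4 for paths 5-8.
#' @slot rawOutputs per-frame raw value driving the decision (ok-class
#'   probability, FIS output, or a score matrix for path5).
#' @slot models list of trained model handles.
#' @export
setClass("PathResult",
  representation(pathId = "integer", predictions = "ANY",
                 rawOutputs = "ANY", models = "list"),
  validity = function(object) {
    if (!object@pathId %in% 1:8) return("pathId must be in 1..8")
    p <- object@predictions
    if (object@pathId <= 4L) {
      if (!is.character(p) || !all(p %in% BINARY_LEVELS))
        return("binary paths must predict 'ok'/'no_ok'")
    } else {
      if (!all(p %in% GROUP_LEVELS))
        return("multi-class paths must predict groups 1..4")
    }
    TRUE
  })

#' Evaluation report
#'
#' Confusion matrix, accuracy, precision, recall, f1 and the unweighted
#' Cohen's kappa with its verbal agreement category, for one evaluation.
#'
#' @slot confusion square count matrix, rows = reference, columns = prediction.
#' @slot acc,precision,recall,f1 numeric in [0,1] (macro-averaged for
#'   multi-class, ok-class for binary).
#' @slot kappa numeric in [-1,1].
#' @slot agreement one of Poor, Slight, Fair, Moderate, Substantial, Perfect.
#' @export
setClass("EvalReport",
  representation(confusion = "matrix", acc = "numeric", precision = "numeric",
                 recall = "numeric", f1 = "numeric", kappa = "numeric",
                 agreement = "character"),
  validity = function(object) {
    m <- object@confusion
    if (nrow(m) != ncol(m)) return("confusion matrix must be square")
    if (any(m < 0)) return("confusion counts must be non-negative")
    for (s in c("acc", "precision", "recall", "f1"))
      if (!is.na(slot(object, s)) && (slot(object, s) < 0 || slot(object, s) > 1))
        return(sprintf("%s must lie in [0,1]", s))
    if (object@kappa < -1 - 1e-12 || object@kappa > 1 + 1e-12)
      return("kappa must lie in [-1,1]")
    TRUE
  })

#' Inter/intra-observer agreement report
#'
#' @slot confusion 2x2 count matrix over ok/no_ok.
#' @slot kappa unweighted Cohen's kappa.
#' @slot category verbal agreement category.
#' @slot raters length-2 character naming the compared annotators.
#' @export
setClass("AgreementReport",
  representation(confusion = "matrix", kappa = "numeric",
                 category = "character", raters = "character"),
  validity = function(object) {
    if (!identical(dim(object@confusion), c(2L, 2L)))
      return("agreement confusion matrix must be 2 x 2")
    if (any(object@confusion < 0)) return("confusion counts must be non-negative")
    TRUE
  })

setMethod("show", "MembershipFunction", function(object) {
  cat(sprintf("MembershipFunction: %s (%s)\n", object@kind,
              paste(format(object@breakpoints), collapse = ", ")))
})

setMethod("show", "FisSpec", function(object) {
  cat("Mamdani FisSpec\n")
  cat(sprintf("  input sets : %s\n", paste(names(object@inputSets), collapse = ", ")))
  cat(sprintf("  output sets: %s\n", paste(names(object@outputSets), collapse = ", ")))
  cat(sprintf("  rules      : %d (min-AND, min-implication, max-aggregation, centroid)\n",
              nrow(object@rules)))
})

setMethod("show", "HfusDataset", function(object) {
  n <- nrow(object@frameInfo)
  loaded <- sum(!vapply(object@pixels, is.null, logical(1)))
  cat(sprintf("HfusDataset: %d frames (%d with pixels), %d session(s)\n",
              n, loaded, length(unique(object@frameInfo$session_id))))
  if (n > 0) {
    gs <- groupSizeSummary(object@annotations)
    cat("  group sizes:", paste(sprintf("%d=%d", 1:4, gs), collapse = " "), "\n")
  }
})

setMethod("show", "PathResult", function(object) {
  cat(sprintf("PathResult: path%d (%s), %d predictions, %d model(s)\n",
              object@pathId, if (object@pathId <= 4) "binary" else "4-group",
              length(object@predictions), length(object@models)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: ACC %.4f  precision %.4f  recall %.4f  f1 %.4f\n",
              object@acc, object@precision, object@recall, object@f1))
  cat(sprintf("  kappa %.4f (%s agreement)\n", object@kappa, object@agreement))
})

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport %s vs %s: kappa %.4f (%s)\n",
              object@raters[1], object@raters[2], object@kappa, object@category))
})
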
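#' Create external k-fold splits with an inner 4:1 train/validation split
#'
#' Frames are shuffled and dealt into k folds whose sizes differ by at most
#' one. For each fold, the non-test frames are further split 4:1 into
#' training and validation subsets (sizes within one frame of the exact
#' ratio). Splitting is at frame level.
#'
#' @param n number of frames.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the shuffle.
#' @return list with elements \code{k}, \code{assignments} (per-frame fold
#'   index) and \code{folds}: per fold a list with \code{test},
#'   \code{train}, \code{validation} index vectors.
#' @export
makeCvFolds <- function(n, k = 5L, seed = 1L) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < k) stop(sprintf("cannot make %d folds from %d frames", k, n))
  set.seed(seed)
  ord <- sample.int(n)
  assignments <- integer(n)
  assignments[ord] <- rep_len(seq_len(k), n)
  folds <- lapply(seq_len(k), function(f) {
    test <- which(assignments == f)
    rest <- setdiff(ord, test)          # keep shuffled order for the 4:1 cut
    nVal <- max(1L, round(length(rest) / 5))
    list(test = test,
         validation = sort(rest[seq_len(nVal)]),
         train = sort(rest[-seq_len(nVal)]))
  })
  list(k = k, assignments = assignments, folds = folds)
}

.perClassPRF <- function(m) {
  # m: confusion with rows = reference, cols = prediction
  tp <- diag(m)
  prec <- ifelse(colSums(m) > 0, tp / colSums(m), 0)
  rec <- ifelse(rowSums(m) > 0, tp / rowSums(m), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(precision = prec, recall = rec, f1 = f1)
}

#' Classification metrics for one evaluation
#'
#' Accuracy, precision, recall and f1 from the confusion matrix (rows =
#' reference, columns = prediction). For binary ok/no_ok labels the
#' precision/recall/f1 are reported for the ok class (the class the frame
#' selection exists to find); for the 4-group labels they are
#' macro-averaged over classes. Cohen's kappa and its verbal category are
#' included.
#'
#' @param yTrue,yPred equal-length label vectors.
#' @param labels label order; defaults to \code{binaryLevels()} for binary
#'   input, groups 1..4 otherwise.
#' @return an \linkS4class{EvalReport}.
#' @export
computeMetrics <- function(yTrue, yPred, labels = NULL) {
  if (length(yTrue) == 0L) stop("cannot evaluate an empty label sequence")
  if (length(yTrue) != length(yPred))
    stop("reference and prediction lengths differ")
  if (is.null(labels)) {
    labels <- if (all(c(yTrue, yPred) %in% BINARY_LEVELS)) BINARY_LEVELS
              else GROUP_LEVELS
  }
  m <- confusionCounts(yTrue, yPred, labels = labels)
  acc <- sum(diag(m)) / sum(m)
  prf <- .perClassPRF(m)
  if (identical(as.character(labels), BINARY_LEVELS)) {
    i <- match("ok", as.character(labels))
    precision <- prf$precision[i]; recall <- prf$recall[i]; f1 <- prf$f1[i]
  } else {
    precision <- mean(prf$precision); recall <- mean(prf$recall)
    f1 <- mean(prf$f1)
  }
  k <- cohenKappa(m)
  new("EvalReport", confusion = m, acc = acc,
      precision = unname(precision), recall = unname(recall),
      f1 = unname(f1), kappa = k, agreement = interpretKappa(k))
}

#' Evaluate a path result against reference labels
#'
#' @param result a \linkS4class{PathResult} (or a plain prediction vector).
#' @param reference reference labels of matching arity (binary for paths
#'   1-4, groups for 5-8).
#' @param idx optional frame indices to restrict the comparison to (e.g.
#'   the reliable frames for the reliable-labels evaluation).
#' @return an \linkS4class{EvalReport}.
#' @export
evaluatePath <- function(result, reference, idx = NULL) {
  pred <- if (is(result, "PathResult")) result@predictions else result
  if (!is.null(idx)) {
    pred <- pred[idx]
    if (length(reference) != length(idx)) reference <- reference[idx]
  }
  binPred <- all(pred %in% BINARY_LEVELS)
  binRef <- all(reference %in% BINARY_LEVELS)
  if (binPred != binRef)
    stop("prediction and reference arity differ (binary vs group labels)")
  computeMetrics(reference, pred)
}

#' Reference labels for a named evaluation
#'
#' The evaluations compare a path's output against expert-derived labels:
#' the reliable-labels evaluation uses only the unanimous frames (groups 1
#' and 4) with their unanimous binary label; the binary evaluations use the
#' majority-vote label of every frame; the multi-class evaluations use the
#' fused group label; the per-expert evaluations use a single expert's
#' column.
#'
#' @param rule one of \code{"reliable"}, \code{"majority"}, \code{"group"},
#'   \code{"expert1"}, \code{"expert2"}, \code{"expert3"}.
#' @param ann n x 3 annotation matrix.
#' @return list with \code{idx} (frame indices the evaluation covers) and
#'   \code{labels} (their reference labels).
#' @export
referenceLabels <- function(rule, ann) {
  ann <- .asTripleMatrix(ann)
  groups <- assignGroup(ann)
  switch(rule,
    reliable = {
      idx <- which(groups %in% c(1L, 4L))
      list(idx = idx, labels = groupToBinary(groups[idx]))
    },
    majority = list(idx = seq_len(nrow(ann)), labels = majorityVote(ann)),
    group = list(idx = seq_len(nrow(ann)), labels = groups),
    expert1 = list(idx = seq_len(nrow(ann)), labels = unname(ann[, 1])),
    expert2 = list(idx = seq_len(nrow(ann)), labels = unname(ann[, 2])),
    expert3 = list(idx = seq_len(nrow(ann)), labels = unname(ann[, 3])),
    stop(sprintf("unknown reference rule '%s'", rule)))
}

#' Numbered evaluations
#'
#' The study's ten numbered evaluations pair a processing path with a
#' reference rule. Evaluation 1 scores the reliable-labels model on the
#' unanimous frames only; evaluation 4 scores the per-expert models against
#' their own expert's labels (backbone selection); evaluations 2, 3, 5, 6
#' score paths 1-4 against the majority-vote labels; evaluations 7-10 score
#' paths 5-8 against the fused group labels.
#'
#' @param evalId integer 1..10.
#' @return list with elements \code{path} (the path to run; NA for the
#'   per-expert evaluation 4) and \code{rule} (reference rule name).
#' @export
evaluationPlan <- function(evalId) {
  plans <- list(
    `1` = list(path = 1L, rule = "reliable"),
    `2` = list(path = 1L, rule = "majority"),
    `3` = list(path = 2L, rule = "majority"),
    `4` = list(path = NA_integer_, rule = "expert"),
    `5` = list(path = 3L, rule = "majority"),
    `6` = list(path = 4L, rule = "majority"),
    `7` = list(path = 5L, rule = "group"),
    `8` = list(path = 6L, rule = "group"),
    `9` = list(path = 7L, rule = "group"),
    `10` = list(path = 8L, rule = "group"))
  p <- plans[[as.character(as.integer(evalId))]]
  if (is.null(p)) stop(sprintf("unknown evaluation id %s", evalId))
  p
}

#' Run a processing path under external k-fold cross-validation
#'
#' Every frame is predicted exactly once, by the model(s) of the fold in
#' which it is in the test set. All models of a multi-model path are
#' trained on the same fold split, so the voting compares like with like.
#'
#' @param ds an \linkS4class{HfusDataset} with pixels.
#' @param pathId integer 1..8.
#' @param cfg a [trainConfig()].
#' @param k number of external folds (default 5).
#' @param seed seed for the fold shuffle (model seeds come from
#'   \code{cfg$seed}).
#' @param fis optional \linkS4class{FisSpec} for paths 4/8.
#' @return a \linkS4class{PathResult} covering all frames, with an extra
#'   \code{foldAssignments} attribute on the predictions.
#' @export
crossValidatePath <- function(ds, pathId, cfg = trainConfig(), k = 5L,
                              seed = 1L, fis = NULL) {
  n <- nFrames(ds)
  cv <- makeCvFolds(n, k = k, seed = seed)
  pathId <- as.integer(pathId)
  pred <- if (pathId <= 4L) character(n) else integer(n)
  raw <- NULL
  models <- list()
  baseSeed <- cfg$seed
  for (f in seq_len(cv$k)) {
    fold <- cv$folds[[f]]
    cfgF <- cfg
    cfgF$seed <- as.integer(baseSeed + 10L * f)
    res <- runPath(ds, pathId, cfgF, fis = fis,
                   trainIdx = fold$train, predictIdx = fold$test,
                   valIdx = fold$validation)
    pred[fold$test] <- res@predictions
    if (is.null(raw)) {
      raw <- if (is.matrix(res@rawOutputs)) {
        matrix(vector(mode = storage.mode(res@rawOutputs), length = 1L),
               nrow = n, ncol = ncol(res@rawOutputs))
      } else numeric(n)
    }
    if (is.matrix(raw)) raw[fold$test, ] <- res@rawOutputs
    else raw[fold$test] <- res@rawOutputs
    models[[f]] <- res@models
  }
  attr(pred, "foldAssignments") <- cv$assignments
  new("PathResult", pathId = pathId, predictions = pred,
      rawOutputs = raw, models = models)
}

#' Flatten an evaluation report for CSV export
#'
#' @param report an \linkS4class{EvalReport}.
#' @param id optional evaluation identifier column.
#' @return a one-row data.frame mirroring the summary-table columns
#'   (id, acc, precision, recall, f1, kappa, agreement).
#' @export
evalAsDataFrame <- function(report, id = NA_character_) {
  stopifnot(is(report, "EvalReport"))
  data.frame(evaluation = id, acc = report@acc, precision = report@precision,
             recall = report@recall, f1 = report@f1, kappa = report@kappa,
             agreement = report@agreement, stringsAsFactors = FALSE)
}
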
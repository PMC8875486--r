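## The eight processing paths. Paths 1-4 make binary ok/no_ok decisions,
## paths 5-8 assign the four-group consensus labels. Each run trains on the
## frames in `trainIdx` (with `valIdx` used for epoch logging only) and
## predicts every frame in `predictIdx`.

.framesOf <- function(ds, idx) ds@pixels[idx]

.trainBinary <- function(ds, trainIdx, valIdx, labels, cfg, seedShift = 0L,
                         valLabels = NULL) {
  cfg$seed <- as.integer(cfg$seed + seedShift)
  cfg$nClasses <- 2L
  model <- buildModel(cfg)
  useVal <- length(valIdx) > 0L && !is.null(valLabels)
  trainModel(model, .framesOf(ds, trainIdx), labels,
             valFrames = if (useVal) .framesOf(ds, valIdx) else NULL,
             valLabels = if (useVal) valLabels else NULL)
}

.trainExpertModels <- function(ds, trainIdx, valIdx, cfg) {
  ann <- annotations(ds)
  lapply(1:3, function(e)
    .trainBinary(ds, trainIdx, valIdx, ann[trainIdx, e], cfg, seedShift = e))
}

.okProbs <- function(model, ds, predictIdx) {
  scoreToOkProbability(predictScores(model, .framesOf(ds, predictIdx)))
}

#' Run one of the eight processing paths
#'
#' Binary paths: path 1 trains a single model on the reliable frames only
#' (unanimous groups 1 and 4) with their unanimous labels; path 2 trains on
#' all frames with majority-voted labels; path 3 trains one model per expert
#' and majority-votes the three predicted labels; path 4 trains per-expert
#' models and fuses their ok-scores with the Mamdani FIS, thresholded at
#' 0.5. Multi-class paths: path 5 trains a single 4-group model on the fused
#' group labels; path 6 reuses the path-1 training scheme and maps the
#' ok-score through the uniform output bins; path 7 applies the group-label
#' scheme to the triple of per-expert predicted labels; path 8 maps the FIS
#' output of the per-expert scores through the uniform bins.
#'
#' Each per-expert model uses seed \code{cfg$seed + expert index} so
#' multi-model paths are reproducible.
#'
#' @param ds an \linkS4class{HfusDataset} with pixels loaded.
#' @param pathId integer 1..8.
#' @param cfg a [trainConfig()]; \code{nClasses} is set by the path.
#' @param fis a \linkS4class{FisSpec} for paths 4 and 8 (defaults to the
#'   shipped specifications).
#' @param trainIdx,predictIdx frame indices used for training and
#'   prediction (default: all frames, as in a fit-then-apply run).
#' @param valIdx optional indices of a validation subset (logging only).
#' @return a \linkS4class{PathResult}.
#' @export
runPath <- function(ds, pathId, cfg = trainConfig(), fis = NULL,
                    trainIdx = seq_len(nFrames(ds)),
                    predictIdx = seq_len(nFrames(ds)),
                    valIdx = integer(0)) {
  stopifnot(is(ds, "HfusDataset"))
  pathId <- as.integer(pathId)
  if (!pathId %in% 1:8) stop("pathId must be in 1..8")
  ann <- annotations(ds)
  groups <- assignGroup(ann)
  if (is.null(fis)) fis <- if (pathId == 4L) defaultBinaryFis() else defaultFourClassFis()

  reliableTrain <- function() {
    rel <- trainIdx[groups[trainIdx] %in% c(1L, 4L)]
    if (length(rel) == 0L)
      stop("path requires reliable (unanimous) frames but none are in the training set")
    .trainBinary(ds, rel, valIdx, groupToBinary(groups[rel]), cfg)
  }

  res <- switch(as.character(pathId),
    "1" = {
      model <- reliableTrain()
      p <- .okProbs(model, ds, predictIdx)
      list(pred = thresholdBinary(p), raw = p, models = list(model))
    },
    "2" = {
      labels <- majorityVote(ann[trainIdx, , drop = FALSE])
      model <- .trainBinary(ds, trainIdx, valIdx, labels, cfg)
      p <- .okProbs(model, ds, predictIdx)
      list(pred = thresholdBinary(p), raw = p, models = list(model))
    },
    "3" = {
      models <- .trainExpertModels(ds, trainIdx, valIdx, cfg)
      labs <- vapply(models, function(m)
        thresholdBinary(.okProbs(m, ds, predictIdx)), character(length(predictIdx)))
      labs <- matrix(labs, ncol = 3L)
      list(pred = majorityVote(labs), raw = labs, models = models)
    },
    "4" = {
      models <- .trainExpertModels(ds, trainIdx, valIdx, cfg)
      probs <- vapply(models, .okProbs, numeric(length(predictIdx)),
                      ds = ds, predictIdx = predictIdx)
      probs <- matrix(probs, ncol = 3L)
      y <- fisOutput(probs, fis)
      list(pred = thresholdBinary(y), raw = y, models = models)
    },
    "5" = {
      cfg$nClasses <- 4L
      cfg$seed <- as.integer(cfg$seed)
      model <- buildModel(cfg)
      model <- trainModel(model, .framesOf(ds, trainIdx), groups[trainIdx])
      sc <- predictScores(model, .framesOf(ds, predictIdx))
      list(pred = as.integer(max.col(sc, ties.method = "first")),
           raw = sc, models = list(model))
    },
    "6" = {
      model <- reliableTrain()
      p <- .okProbs(model, ds, predictIdx)
      list(pred = mapOutputToGroup(p), raw = p, models = list(model))
    },
    "7" = {
      models <- .trainExpertModels(ds, trainIdx, valIdx, cfg)
      labs <- vapply(models, function(m)
        thresholdBinary(.okProbs(m, ds, predictIdx)), character(length(predictIdx)))
      labs <- matrix(labs, ncol = 3L)
      list(pred = assignGroup(labs), raw = labs, models = models)
    },
    "8" = {
      models <- .trainExpertModels(ds, trainIdx, valIdx, cfg)
      probs <- vapply(models, .okProbs, numeric(length(predictIdx)),
                      ds = ds, predictIdx = predictIdx)
      probs <- matrix(probs, ncol = 3L)
      y <- fisOutput(probs, fis)
      list(pred = mapOutputToGroup(y), raw = y, models = models)
    })
  new("PathResult", pathId = pathId, predictions = res$pred,
      rawOutputs = res$raw, models = res$models)
}

#' Voting-stage decisions from per-expert model scores
#'
#' The pure fusion stage shared by paths 3/4/7/8, separated from model
#' training so it can be studied (and verified) on its own: given the three
#' ok-probabilities, returns the majority-vote label (v1), the FIS decision
#' (v2), the group label from the predicted-label triple, and the group
#' label from the FIS output bins.
#'
#' @param probs n x 3 matrix of per-expert ok-probabilities.
#' @param fis a \linkS4class{FisSpec}.
#' @return data.frame with columns \code{vote_label, fis_output, fis_label,
#'   vote_group, fis_group}.
#' @export
votingDecisions <- function(probs, fis = defaultBinaryFis()) {
  probs <- matrix(probs, ncol = 3L)
  labs <- matrix(thresholdBinary(as.vector(probs)), ncol = 3L)
  y <- fisOutput(probs, fis)
  data.frame(vote_label = majorityVote(labs),
             fis_output = y,
             fis_label = thresholdBinary(y),
             vote_group = assignGroup(labs),
             fis_group = mapOutputToGroup(y),
             stringsAsFactors = FALSE)
}

#' @describeIn runPath predictions accessor.
#' @param result a \linkS4class{PathResult}.
#' @export
pathPredictions <- function(result) result@predictions

#' @describeIn runPath raw outputs accessor (ok-probabilities, FIS outputs
#'   or score matrix).
#' @export
pathRawOutputs <- function(result) result@rawOutputs
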
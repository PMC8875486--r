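## Training/prediction wrappers over the engine in cnn-engine.R.

## A leading chain of parameter-free layers (pooling only) can be applied to
## the training set once instead of every epoch. Returns the prefix length P
## (possibly 0) such that layers 1..P are pure pooling and every later layer
## reads only from nodes > P (or exactly P).
.fixedPrefixLength <- function(layers) {
  P <- 0L
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    if (ly$type %in% c("avgpool", "maxpool") && length(ly$from) == 1L &&
        ly$from == l - 1L) P <- l else break
  }
  if (P == 0L) return(0L)
  for (l in (P + 1L):length(layers)) {
    if (any(layers[[l]]$from < P & layers[[l]]$from >= 0L) ||
        any(layers[[l]]$from == 0L)) return(0L)
  }
  P
}

.applyPrefix <- function(layers, P, frames, backbone, batchSize) {
  n <- length(frames)
  outList <- vector("list", ceiling(n / batchSize))
  bi <- 0L
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(n, start + batchSize - 1L)
    X <- .preprocessBatch(frames[idx], backbone)
    fw <- .graphForward(layers[seq_len(P)], X)
    bi <- bi + 1L
    outList[[bi]] <- fw$outs[[P]]
  }
  d <- dim(outList[[1]])
  out <- array(0, c(d[1], d[2], d[3], n))
  at <- 0L
  for (part in outList) {
    k <- dim(part)[4]
    out[, , , at + seq_len(k)] <- part
    at <- at + k
  }
  out
}

.shiftLayers <- function(layers, P) {
  if (P == 0L) return(layers)
  sub <- layers[(P + 1L):length(layers)]
  lapply(sub, function(ly) {
    ly$from <- ifelse(ly$from == P, 0L, ly$from - P)
    ly
  })
}

.batchLoss <- function(logits, yIdx) {
  p <- .softmax(logits)
  eps <- 1e-12
  n <- nrow(p)
  loss <- -mean(log(p[cbind(seq_len(n), yIdx)] + eps))
  acc <- mean(max.col(p, ties.method = "first") == yIdx)
  Yhot <- matrix(0, n, ncol(p))
  Yhot[cbind(seq_len(n), yIdx)] <- 1
  list(loss = loss, acc = acc, dLogits = (p - Yhot) / n)
}

.evalOn <- function(layers, X, yIdx) {
  fw <- .graphForward(layers, X, train = FALSE)
  logits <- fw$outs[[length(layers)]]
  p <- .softmax(logits)
  eps <- 1e-12
  list(loss = -mean(log(p[cbind(seq_along(yIdx), yIdx)] + eps)),
       acc = mean(max.col(p, ties.method = "first") == yIdx))
}

#' Train a CNN model
#'
#' Stochastic gradient descent with momentum on the categorical
#' cross-entropy, using the hyperparameters stored in the model's
#' configuration (batch size, learning rate, momentum, epochs, seed).
#' Frozen convolution layers are excluded from the update, so their
#' parameters are bit-identical before and after training. Training is
#' deterministic given the seed. The per-epoch log (loss/accuracy, plus
#' validation loss/accuracy when a validation set is given) has exactly
#' \code{epochs} rows.
#'
#' @param model a \linkS4class{CnnModel} from [buildModel()].
#' @param frames list of 224 x 224 x 3 pixel arrays.
#' @param labels per-frame labels matching the model's classes
#'   (ok/no_ok or group 1..4).
#' @param valFrames,valLabels optional validation set, disjoint from the
#'   training frames.
#' @param epochs override of \code{cfg$epochs} (e.g. for quick runs).
#' @return the trained \linkS4class{CnnModel} (log in \code{trainingLog()}).
#' @export
trainModel <- function(model, frames, labels, valFrames = NULL,
                       valLabels = NULL, epochs = NULL) {
  stopifnot(is(model, "CnnModel"))
  cfg <- model@cfg
  if (is.null(epochs)) epochs <- cfg$epochs
  if (length(frames) == 0L) stop("empty training set")
  if (length(frames) != length(labels))
    stop("frames and labels differ in length")
  yIdx <- match(as.character(labels), model@classes)
  if (anyNA(yIdx))
    stop(sprintf("labels outside the model's classes (%s)",
                 paste(model@classes, collapse = ", ")))
  present <- sort(unique(yIdx))
  if (length(present) < length(model@classes))
    warning(sprintf("training labels cover only %d of %d classes",
                    length(present), length(model@classes)))
  if (epochs == 0L) {
    model@log <- model@log[0, ]
    return(model)
  }
  layers <- model@layers
  P <- .fixedPrefixLength(layers)
  feats <- if (P > 0L) {
    .applyPrefix(layers, P, frames, cfg$backbone, cfg$batchSize)
  } else NULL
  sub <- .shiftLayers(layers, P)
  valFeats <- NULL; valIdx <- NULL
  if (!is.null(valFrames) && length(valFrames) > 0L) {
    valIdx <- match(as.character(valLabels), model@classes)
    valFeats <- if (P > 0L) {
      .applyPrefix(layers, P, valFrames, cfg$backbone, cfg$batchSize)
    } else .preprocessBatch(valFrames, cfg$backbone)
  }
  getX <- function(idx) {
    if (P > 0L) feats[, , , idx, drop = FALSE]
    else .preprocessBatch(frames[idx], cfg$backbone)
  }
  n <- length(frames)
  set.seed(cfg$seed + 1L)
  velocity <- vector("list", length(sub))
  logRows <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    epLoss <- 0; epAcc <- 0; seen <- 0L
    for (start in seq(1L, n, by = cfg$batchSize)) {
      idx <- ord[start:min(n, start + cfg$batchSize - 1L)]
      # drop an undersized remainder batch (unless it is the only one):
      # batch statistics of a handful of frames destabilize the bn layers
      # and their gradients
      if (start > 1L && length(idx) < max(2L, cfg$batchSize %/% 2L)) next
      X <- getX(idx)
      fw <- .graphForward(sub, X, train = TRUE, keep = TRUE)
      logits <- fw$outs[[length(sub)]]
      bl <- .batchLoss(logits, yIdx[idx])
      epLoss <- epLoss + bl$loss * length(idx)
      epAcc <- epAcc + bl$acc * length(idx)
      seen <- seen + length(idx)
      grads <- .graphBackward(sub, X, fw$outs, fw$caches, bl$dLogits)
      for (l in seq_along(sub)) {
        ly <- sub[[l]]
        if (!isTRUE(ly$trainable) || is.null(grads[[l]])) next
        for (pn in names(grads[[l]])) {
          v0 <- if (is.null(velocity[[l]][[pn]])) 0 else velocity[[l]][[pn]]
          v <- cfg$momentum * v0 - cfg$learningRate * grads[[l]][[pn]]
          if (is.null(velocity[[l]])) velocity[[l]] <- list()
          velocity[[l]][[pn]] <- v
          sub[[l]][[pn]] <- sub[[l]][[pn]] + v
        }
      }
    }
    row <- data.frame(epoch = ep, loss = epLoss / seen, acc = epAcc / seen,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(valFeats)) {
      ev <- .evalOn(sub, valFeats, valIdx)
      row$val_loss <- ev$loss; row$val_acc <- ev$acc
    }
    logRows[[ep]] <- row
  }
  # Re-estimate batch-normalization statistics with the final weights: one
  # deterministic pass over the training set, batch statistics averaged
  # with batch-size weights.
  if (any(vapply(sub, function(l) identical(l$type, "bn"), logical(1)))) {
    # pooled first and second moments: mean = sum(w*mu)/W and
    # var = sum(w*(v + mu^2))/W - mean^2, so between-batch mean variation
    # is not lost
    bnSum <- list(); bnN <- 0
    for (start in seq(1L, n, by = cfg$batchSize)) {
      idx <- start:min(n, start + cfg$batchSize - 1L)
      fw <- .graphForward(sub, getX(idx), train = TRUE, keep = TRUE)
      w <- length(idx)
      for (l in seq_along(sub)) {
        if (!identical(sub[[l]]$type, "bn")) next
        key <- as.character(l)
        mu <- fw$caches[[l]]$mu; v <- fw$caches[[l]]$v
        add <- list(m1 = w * mu, m2 = w * (v + mu^2))
        bnSum[[key]] <- if (is.null(bnSum[[key]])) add
                        else list(m1 = bnSum[[key]]$m1 + add$m1,
                                  m2 = bnSum[[key]]$m2 + add$m2)
      }
      bnN <- bnN + w
    }
    for (key in names(bnSum)) {
      l <- as.integer(key)
      m1 <- bnSum[[key]]$m1 / bnN
      sub[[l]]$rmean <- m1
      sub[[l]]$rvar <- pmax(bnSum[[key]]$m2 / bnN - m1^2, 0)
    }
  }
  if (P > 0L) {
    for (l in seq_along(sub)) model@layers[[P + l]] <- local({
      ly <- sub[[l]]
      ly$from <- ifelse(ly$from == 0L, P, ly$from + P)
      ly
    })
  } else model@layers <- sub
  model@log <- do.call(rbind, logRows)
  model
}

#' Predict class-score vectors for frames
#'
#' Runs the forward pass (inference mode) and the softmax; one normalized
#' score vector per frame, columns in the model's class order.
#'
#' @param model a trained \linkS4class{CnnModel}.
#' @param frames list of 224 x 224 x 3 pixel arrays.
#' @param batchSize frames per forward batch.
#' @return numeric matrix n x nClasses; each row sums to 1.
#' @export
predictScores <- function(model, frames, batchSize = 64L) {
  stopifnot(is(model, "CnnModel"))
  if (length(frames) == 0L)
    return(matrix(numeric(0), ncol = length(model@classes),
                  dimnames = list(NULL, model@classes)))
  n <- length(frames)
  out <- matrix(0, nrow = n, ncol = length(model@classes),
                dimnames = list(NULL, model@classes))
  L <- length(model@layers)
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(n, start + batchSize - 1L)
    X <- .preprocessBatch(frames[idx], model@cfg$backbone)
    fw <- .graphForward(model@layers, X, train = FALSE)
    out[idx, ] <- .softmax(fw$outs[[L]])
  }
  out
}

#' Ok-class probability from a binary score vector/matrix
#'
#' @param scores a score matrix from [predictScores()] (2 columns, class
#'   order no_ok/ok) or a single length-2 named score vector.
#' @return numeric vector of ok-class probabilities.
#' @export
scoreToOkProbability <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1,
                                             dimnames = list(NULL, names(scores)))
  if (ncol(scores) != 2L)
    stop("ok-probability is defined for binary score vectors only")
  if (!"ok" %in% colnames(scores))
    stop("score columns must be named with the class order (no_ok, ok)")
  unname(scores[, "ok"])
}

#' @describeIn trainModel per-epoch training log.
#' @export
trainingLog <- function(model) model@log

#' Save / load a model checkpoint
#'
#' Checkpoints use R's native serialization (RDS).
#'
#' @param model a \linkS4class{CnnModel}.
#' @param path file path.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
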
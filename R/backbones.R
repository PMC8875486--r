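#' Trained/trainable CNN model handle
#'
#' @slot layers list of layer specifications (graph with weights).
#' @slot cfg the training configuration list (see [trainConfig()]).
#' @slot classes class labels in score-column order.
#' @slot log per-epoch training log (one row per epoch).
#' @export
setClass("CnnModel",
  representation(layers = "list", cfg = "list", classes = "character",
                 log = "data.frame"))

setMethod("show", "CnnModel", function(object) {
  tab <- modelLayerTable(object)
  nconv <- sum(tab$type == "conv")
  cat(sprintf("CnnModel: backbone '%s', %d classes (%s)\n", object@cfg$backbone,
              length(object@classes), paste(object@classes, collapse = ", ")))
  cat(sprintf("  %d layers, %d conv (%d frozen), %d epochs trained\n",
              nrow(tab), nconv, sum(tab$type == "conv" & !tab$trainable),
              nrow(object@log)))
})

#' Training configuration
#'
#' Captures the transfer-learning regime: SGD with momentum 0.9, categorical
#' cross-entropy, batch size 64, and backbone-specific defaults. For the
#' pretrained-style backbones the defaults follow the reference setup
#' (learning rate 1e-4, 50 epochs, 10 frozen conv layers for VGG16 and 140
#' for DenseNet-201). The \code{tiny_test} backbone is a small
#' trained-from-scratch network for desk-scale runs and uses a larger step
#' size (0.01) and 8 epochs by default.
#'
#' @param backbone one of \code{"tiny_test"}, \code{"vgg16"},
#'   \code{"densenet201"}.
#' @param nClasses 2 (ok/no_ok) or 4 (group labels).
#' @param frozenConvLayers number of leading convolution layers (in
#'   definition order) excluded from training; default depends on backbone.
#' @param learningRate,momentum,batchSize,epochs SGD hyperparameters
#'   (batch size defaults to 64, or 16 for \code{tiny_test}).
#' @param seed integer seed controlling weight initialization and batch
#'   shuffling.
#' @return a named list with class defaults resolved.
#' @export
trainConfig <- function(backbone = c("tiny_test", "vgg16", "densenet201"),
                        nClasses = 2L, frozenConvLayers = NULL,
                        learningRate = NULL, momentum = 0.9,
                        batchSize = NULL, epochs = NULL, seed = 1L) {
  backbone <- match.arg(backbone)
  if (!nClasses %in% c(2L, 4L)) stop("nClasses must be 2 or 4")
  defaults <- list(
    tiny_test = list(frozen = 0L, lr = 0.1, epochs = 8L, batch = 16L),
    vgg16 = list(frozen = 10L, lr = 1e-4, epochs = 50L, batch = 64L),
    densenet201 = list(frozen = 140L, lr = 1e-4, epochs = 50L, batch = 64L))[[backbone]]
  if (is.null(frozenConvLayers)) frozenConvLayers <- defaults$frozen
  if (is.null(learningRate)) learningRate <- defaults$lr
  if (is.null(epochs)) epochs <- defaults$epochs
  if (is.null(batchSize)) batchSize <- defaults$batch
  if (frozenConvLayers < 0) stop("frozenConvLayers must be non-negative")
  list(backbone = backbone, nClasses = as.integer(nClasses),
       frozenConvLayers = as.integer(frozenConvLayers),
       learningRate = learningRate, momentum = momentum,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       seed = as.integer(seed))
}

## ---- architecture tables ---------------------------------------------------

.mkConv <- function(from, k, s, p, cin, cout) {
  list(type = "conv", from = from, k = k, s = s, p = p, cin = cin, cout = cout)
}

.tinyTestArch <- function(nClasses) {
  layers <- list(
    list(type = "avgpool", from = 0L, k = 8L, s = 8L),
    .mkConv(1L, 3L, 1L, 1L, 3L, 8L),
    list(type = "bn", from = 2L, cc = 8L),
    list(type = "relu", from = 3L),
    list(type = "maxpool", from = 4L, k = 2L, s = 2L, p = 0L),
    .mkConv(5L, 3L, 1L, 1L, 8L, 16L),
    list(type = "bn", from = 6L, cc = 16L),
    list(type = "relu", from = 7L),
    list(type = "gap", from = 8L),
    list(type = "dense", from = 9L, cin = 16L, cout = nClasses))
  layers
}

.vgg16Arch <- function(nClasses) {
  blocks <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                 c(512, 512, 512), c(512, 512, 512))
  layers <- list()
  cur <- 0L; cin <- 3L
  add <- function(l) { layers[[length(layers) + 1L]] <<- l; length(layers) }
  for (b in blocks) {
    for (cout in b) {
      cur <- add(.mkConv(cur, 3L, 1L, 1L, cin, as.integer(cout)))
      cur <- add(list(type = "relu", from = cur))
      cin <- as.integer(cout)
    }
    cur <- add(list(type = "maxpool", from = cur, k = 2L, s = 2L, p = 0L))
  }
  cur <- add(list(type = "gap", from = cur))
  add(list(type = "dense", from = cur, cin = cin, cout = nClasses))
  layers
}

.densenet201Arch <- function(nClasses, growth = 32L) {
  layers <- list()
  add <- function(l) { layers[[length(layers) + 1L]] <<- l; length(layers) }
  cur <- add(.mkConv(0L, 7L, 2L, 3L, 3L, 64L))
  ch <- 64L
  cur <- add(list(type = "bn", from = cur, cc = ch))
  cur <- add(list(type = "relu", from = cur))
  cur <- add(list(type = "maxpool", from = cur, k = 3L, s = 2L, p = 1L))
  blockSizes <- c(6L, 12L, 48L, 32L)
  for (bi in seq_along(blockSizes)) {
    for (j in seq_len(blockSizes[bi])) {
      top <- cur
      x <- add(list(type = "bn", from = top, cc = ch))
      x <- add(list(type = "relu", from = x))
      x <- add(.mkConv(x, 1L, 1L, 0L, ch, 4L * growth))
      x <- add(list(type = "bn", from = x, cc = 4L * growth))
      x <- add(list(type = "relu", from = x))
      x <- add(.mkConv(x, 3L, 1L, 1L, 4L * growth, growth))
      cur <- add(list(type = "concat", from = c(top, x)))
      ch <- ch + growth
    }
    if (bi < length(blockSizes)) {
      x <- add(list(type = "bn", from = cur, cc = ch))
      x <- add(list(type = "relu", from = x))
      ch2 <- as.integer(ch %/% 2L)
      x <- add(.mkConv(x, 1L, 1L, 0L, ch, ch2))
      cur <- add(list(type = "avgpool", from = x, k = 2L, s = 2L))
      ch <- ch2
    }
  }
  cur <- add(list(type = "bn", from = cur, cc = ch))
  cur <- add(list(type = "relu", from = cur))
  cur <- add(list(type = "gap", from = cur))
  add(list(type = "dense", from = cur, cin = ch, cout = nClasses))
  layers
}

.backboneConvCount <- function(backbone) {
  switch(backbone, tiny_test = 2L, vgg16 = 13L, densenet201 = 200L)
}

## ---- model construction ----------------------------------------------------

.initLayers <- function(layers, frozen) {
  convIdx <- 0L
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    if (ly$type == "conv") {
      convIdx <- convIdx + 1L
      fanIn <- ly$k * ly$k * ly$cin
      ly$W <- matrix(stats::rnorm(fanIn * ly$cout, sd = sqrt(2 / fanIn)),
                     nrow = fanIn, ncol = ly$cout)
      ly$b <- numeric(ly$cout)
      ly$convIdx <- convIdx
      ly$trainable <- convIdx > frozen
    } else if (ly$type == "bn") {
      ly$gamma <- rep(1, ly$cc); ly$beta <- numeric(ly$cc)
      ly$rmean <- numeric(ly$cc); ly$rvar <- rep(1, ly$cc)
      ly$trainable <- TRUE
    } else if (ly$type == "dense") {
      ly$W <- matrix(stats::rnorm(ly$cin * ly$cout, sd = sqrt(2 / ly$cin)),
                     nrow = ly$cin, ncol = ly$cout)
      ly$b <- numeric(ly$cout)
      ly$trainable <- TRUE
    } else {
      ly$trainable <- FALSE
    }
    layers[[l]] <- ly
  }
  layers
}

#' Build a CNN classifier
#'
#' Instantiates the requested backbone with its classification head sized
#' for \code{cfg$nClasses} and the first \code{cfg$frozenConvLayers}
#' convolution layers (in definition order) marked non-trainable. Weights
#' are He-initialized from \code{cfg$seed}; pretrained weights can be
#' restored with [loadModel()].
#'
#' @param cfg a configuration from [trainConfig()].
#' @return a \linkS4class{CnnModel}.
#' @export
buildModel <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$backbone))
  nConv <- .backboneConvCount(cfg$backbone)
  if (is.null(nConv)) stop(sprintf("unknown backbone '%s'", cfg$backbone))
  if (cfg$frozenConvLayers > nConv)
    stop(sprintf("cannot freeze %d conv layers: %s has %d",
                 cfg$frozenConvLayers, cfg$backbone, nConv))
  arch <- switch(cfg$backbone,
                 tiny_test = .tinyTestArch(cfg$nClasses),
                 vgg16 = .vgg16Arch(cfg$nClasses),
                 densenet201 = .densenet201Arch(cfg$nClasses))
  set.seed(cfg$seed)
  layers <- .initLayers(arch, cfg$frozenConvLayers)
  classes <- if (cfg$nClasses == 2L) BINARY_LEVELS else as.character(1:4)
  new("CnnModel", layers = layers, cfg = cfg, classes = classes,
      log = data.frame(epoch = integer(0), loss = numeric(0),
                       acc = numeric(0), val_loss = numeric(0),
                       val_acc = numeric(0)))
}

#' Summary table of a model's layers
#'
#' @param model a \linkS4class{CnnModel}.
#' @return data.frame with layer index, type, conv ordinal (NA for
#'   non-conv layers) and trainability.
#' @export
modelLayerTable <- function(model) {
  stopifnot(is(model, "CnnModel"))
  data.frame(
    layer = seq_along(model@layers),
    type = vapply(model@layers, `[[`, character(1), "type"),
    conv_index = vapply(model@layers, function(l)
      if (!is.null(l$convIdx)) l$convIdx else NA_integer_, integer(1)),
    trainable = vapply(model@layers, function(l)
      isTRUE(l$trainable), logical(1)))
}

## Backbone-native input normalization: tiny_test scales to [0,1]; the
## ImageNet-pretrained-style backbones additionally standardize per channel
## with the ImageNet statistics.
.preprocessBatch <- function(frames, backbone) {
  n <- length(frames)
  d <- dim(frames[[1]])
  X <- array(0, c(d[1], d[2], d[3], n))
  for (i in seq_len(n)) X[, , , i] <- frames[[i]]
  X <- X / 255
  if (backbone %in% c("vgg16", "densenet201")) {
    mu <- c(0.485, 0.456, 0.406); sdv <- c(0.229, 0.224, 0.225)
    for (ch in 1:3) X[, , ch, ] <- (X[, , ch, ] - mu[ch]) / sdv[ch]
  }
  X
}
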
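## Compact CNN engine: feature maps are arrays (h, w, c, n); convolution is
## im2col + matrix multiplication; the layer graph is a list where each layer
## names its input node(s) (`from`, 0 = network input), so channel
## concatenation (dense connectivity) is supported. Written for small
## desk-scale problems; everything is plain double arithmetic, so results
## are bit-reproducible given the RNG seed.

.padArray <- function(X, p, fill = 0) {
  if (p == 0) return(X)
  d <- dim(X)
  Xp <- array(fill, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  Xp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- X
  Xp
}

.im2col <- function(X, k, s, p) {
  Xp <- .padArray(X, p)
  d <- dim(Xp); hp <- d[1]; wp <- d[2]; cc <- d[3]; n <- d[4]
  oh <- (hp - k) %/% s + 1L; ow <- (wp - k) %/% s + 1L
  M <- matrix(0, nrow = oh * ow * n, ncol = k * k * cc)
  b <- 0L
  for (kw in seq_len(k)) for (kh in seq_len(k)) {
    S <- Xp[seq.int(kh, by = s, length.out = oh),
            seq.int(kw, by = s, length.out = ow), , , drop = FALSE]
    S <- aperm(S, c(1, 2, 4, 3))
    dim(S) <- c(oh * ow * n, cc)
    M[, b + seq_len(cc)] <- S
    b <- b + cc
  }
  list(M = M, oh = oh, ow = ow)
}

.col2im <- function(dM, h, w, cc, n, k, s, p, oh, ow) {
  dXp <- array(0, c(h + 2 * p, w + 2 * p, cc, n))
  b <- 0L
  for (kw in seq_len(k)) for (kh in seq_len(k)) {
    dS <- dM[, b + seq_len(cc), drop = FALSE]
    dim(dS) <- c(oh, ow, n, cc)
    dS <- aperm(dS, c(1, 2, 4, 3))
    ih <- seq.int(kh, by = s, length.out = oh)
    iw <- seq.int(kw, by = s, length.out = ow)
    dXp[ih, iw, , ] <- dXp[ih, iw, , , drop = FALSE] + dS
    b <- b + cc
  }
  if (p > 0) dXp[(p + 1):(p + h), (p + 1):(p + w), , , drop = FALSE] else dXp
}

.channelMatrix <- function(X) {
  # (h, w, c, n) -> (h*w*n, c)
  d <- dim(X)
  Z <- aperm(X, c(1, 2, 4, 3))
  dim(Z) <- c(d[1] * d[2] * d[4], d[3])
  Z
}

.channelArray <- function(Z, d) {
  dim(Z) <- c(d[1], d[2], d[4], d[3])
  aperm(Z, c(1, 2, 4, 3))
}

## ---- per-layer forward/backward -------------------------------------------

.layerForward <- function(layer, X, train = FALSE) {
  d <- dim(X)
  switch(layer$type,
    conv = {
      ic <- .im2col(X, layer$k, layer$s, layer$p)
      Ym <- ic$M %*% layer$W
      Ym <- Ym + rep(layer$b, each = nrow(Ym))
      Y <- .channelArray(Ym, c(ic$oh, ic$ow, layer$cout, d[4]))
      list(Y = Y, cache = list(M = ic$M, oh = ic$oh, ow = ic$ow, din = d))
    },
    bn = {
      Z <- .channelMatrix(X)
      if (train) {
        mu <- colMeans(Z)
        v <- colMeans(Z^2) - mu^2
      } else {
        mu <- layer$rmean; v <- layer$rvar
      }
      istd <- 1 / sqrt(v + 1e-5)
      xhat <- (Z - rep(mu, each = nrow(Z))) * rep(istd, each = nrow(Z))
      Ym <- xhat * rep(layer$gamma, each = nrow(Z)) + rep(layer$beta, each = nrow(Z))
      list(Y = .channelArray(Ym, d),
           cache = list(xhat = xhat, istd = istd, din = d, mu = mu, v = v))
    },
    relu = list(Y = pmax(X, 0), cache = list(pos = X > 0)),
    maxpool = {
      Xp <- .padArray(X, layer$p, fill = -Inf)
      dp <- dim(Xp)
      oh <- (dp[1] - layer$k) %/% layer$s + 1L
      ow <- (dp[2] - layer$k) %/% layer$s + 1L
      Y <- array(-Inf, c(oh, ow, d[3], d[4]))
      amax <- array(0L, c(oh, ow, d[3], d[4]))
      j <- 0L
      for (kw in seq_len(layer$k)) for (kh in seq_len(layer$k)) {
        j <- j + 1L
        S <- Xp[seq.int(kh, by = layer$s, length.out = oh),
                seq.int(kw, by = layer$s, length.out = ow), , , drop = FALSE]
        upd <- S > Y
        Y[upd] <- S[upd]
        amax[upd] <- j
      }
      list(Y = Y, cache = list(amax = amax, din = d, oh = oh, ow = ow))
    },
    avgpool = {
      oh <- (d[1] - layer$k) %/% layer$s + 1L
      ow <- (d[2] - layer$k) %/% layer$s + 1L
      Y <- array(0, c(oh, ow, d[3], d[4]))
      for (kw in seq_len(layer$k)) for (kh in seq_len(layer$k)) {
        Y <- Y + X[seq.int(kh, by = layer$s, length.out = oh),
                   seq.int(kw, by = layer$s, length.out = ow), , , drop = FALSE]
      }
      list(Y = Y / (layer$k^2), cache = list(din = d, oh = oh, ow = ow))
    },
    gap = {
      Z <- X
      dim(Z) <- c(d[1] * d[2], d[3] * d[4])
      Y <- t(matrix(colMeans(Z), d[3], d[4]))
      list(Y = Y, cache = list(din = d))
    },
    dense = {
      Y <- X %*% layer$W
      Y <- Y + rep(layer$b, each = nrow(Y))
      list(Y = Y, cache = list(X = X))
    },
    stop(sprintf("unknown layer type '%s'", layer$type)))
}

.layerBackward <- function(layer, dY, cache, needDX = TRUE) {
  switch(layer$type,
    conv = {
      d <- cache$din
      dYm <- .channelMatrix(dY)
      dW <- crossprod(cache$M, dYm)
      db <- colSums(dYm)
      dX <- if (needDX) {
        .col2im(dYm %*% t(layer$W), d[1], d[2], d[3], d[4],
                layer$k, layer$s, layer$p, cache$oh, cache$ow)
      } else NULL
      list(dX = dX, grads = list(W = dW, b = db))
    },
    bn = {
      d <- cache$din
      N <- nrow(cache$xhat)
      dYm <- .channelMatrix(dY)
      dgamma <- colSums(dYm * cache$xhat)
      dbeta <- colSums(dYm)
      dxhat <- dYm * rep(layer$gamma, each = N)
      sums1 <- colSums(dxhat)
      sums2 <- colSums(dxhat * cache$xhat)
      dZ <- (dxhat - rep(sums1 / N, each = N) -
             cache$xhat * rep(sums2 / N, each = N)) * rep(cache$istd, each = N)
      list(dX = .channelArray(dZ, d), grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dX = dY * cache$pos, grads = NULL),
    maxpool = {
      d <- cache$din
      dXp <- array(0, c(d[1] + 2 * layer$p, d[2] + 2 * layer$p, d[3], d[4]))
      j <- 0L
      for (kw in seq_len(layer$k)) for (kh in seq_len(layer$k)) {
        j <- j + 1L
        mask <- cache$amax == j
        if (!any(mask)) next
        contrib <- array(0, dim(dY))
        contrib[mask] <- dY[mask]
        ih <- seq.int(kh, by = layer$s, length.out = cache$oh)
        iw <- seq.int(kw, by = layer$s, length.out = cache$ow)
        dXp[ih, iw, , ] <- dXp[ih, iw, , , drop = FALSE] + contrib
      }
      p <- layer$p
      dX <- if (p > 0) dXp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , , drop = FALSE] else dXp
      list(dX = dX, grads = NULL)
    },
    avgpool = {
      d <- cache$din
      dX <- array(0, d)
      dYk <- dY / (layer$k^2)
      for (kw in seq_len(layer$k)) for (kh in seq_len(layer$k)) {
        ih <- seq.int(kh, by = layer$s, length.out = cache$oh)
        iw <- seq.int(kw, by = layer$s, length.out = cache$ow)
        dX[ih, iw, , ] <- dX[ih, iw, , , drop = FALSE] + dYk
      }
      list(dX = dX, grads = NULL)
    },
    gap = {
      d <- cache$din
      dX <- array(rep(t(dY) / (d[1] * d[2]), each = d[1] * d[2]), d)
      list(dX = dX, grads = NULL)
    },
    dense = list(dX = dY %*% t(layer$W),
                 grads = list(W = crossprod(cache$X, dY), b = colSums(dY))),
    stop("unreachable"))
}

## ---- graph forward / backward ---------------------------------------------

.concatInputs <- function(outs, from, X) {
  pick <- function(i) if (i == 0L) X else outs[[i]]
  if (length(from) == 1L) return(pick(from))
  parts <- lapply(from, pick)
  d1 <- dim(parts[[1]])
  ctot <- sum(vapply(parts, function(a) dim(a)[3], numeric(1)))
  out <- array(0, c(d1[1], d1[2], ctot, d1[4]))
  at <- 0L
  for (a in parts) {
    ca <- dim(a)[3]
    out[, , at + seq_len(ca), ] <- a
    at <- at + ca
  }
  out
}

.graphForward <- function(layers, X, train = FALSE, keep = FALSE) {
  L <- length(layers)
  outs <- vector("list", L)
  caches <- if (keep) vector("list", L) else NULL
  # last layer that consumes each node's output, for memory release
  lastUse <- integer(L)
  for (l in seq_len(L)) for (i in layers[[l]]$from) if (i > 0L) lastUse[i] <- l
  for (l in seq_len(L)) {
    layer <- layers[[l]]
    if (identical(layer$type, "concat")) {
      outs[[l]] <- .concatInputs(outs, layer$from, X)
    } else {
      inp <- .concatInputs(outs, layer$from, X)
      fw <- .layerForward(layer, inp, train = train)
      outs[[l]] <- fw$Y
      if (keep) caches[[l]] <- fw$cache
    }
    if (!keep) for (m in which(lastUse == l)) if (m < l) outs[m] <- list(NULL)
  }
  list(outs = outs, caches = caches)
}

.graphBackward <- function(layers, X, outs, caches, dOut) {
  L <- length(layers)
  gradBuf <- vector("list", L + 1L)   # index i+1 = node i (0 = input)
  addGrad <- function(node, g) {
    i <- node + 1L
    gradBuf[[i]] <<- if (is.null(gradBuf[[i]])) g else gradBuf[[i]] + g
  }
  addGrad(L, dOut)
  paramGrads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dY <- gradBuf[[l + 1L]]
    if (is.null(dY)) next
    layer <- layers[[l]]
    if (identical(layer$type, "concat")) {
      at <- 0L
      for (i in layer$from) {
        src <- if (i == 0L) X else outs[[i]]
        ci <- dim(src)[3]
        addGrad(i, dY[, , at + seq_len(ci), , drop = FALSE])
        at <- at + ci
      }
    } else {
      from <- layer$from
      if (length(from) != 1L) stop("non-concat layer with multiple inputs")
      bw <- .layerBackward(layer, dY, caches[[l]], needDX = from > 0L)
      paramGrads[l] <- list(bw$grads)
      if (from > 0L) addGrad(from, bw$dX)
    }
    gradBuf[l + 1L] <- list(NULL)
  }
  paramGrads
}

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}
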
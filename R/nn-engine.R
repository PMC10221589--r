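# Minimal reverse-mode network engine used by the classifier heads, the
# triplet encoder and the small image CNN. Layers operate on n x d matrices
# (dense path) or n x H x W x C arrays (conv path). All randomness flows
# through the caller-provided seed; training is single-threaded and
# deterministic.

.nnInit <- function(spec, seed) {
  set.seed(seed)
  layers <- lapply(spec, function(s) {
    l <- s
    if (s$type == "dense") {
      l$params <- list(
        W = matrix(stats::rnorm(s$nin * s$nout) * sqrt(2 / s$nin),
                   s$nin, s$nout),
        b = numeric(s$nout))
    } else if (s$type == "conv") {
      fanin <- s$k * s$k * s$cin
      l$params <- list(
        W = matrix(stats::rnorm(fanin * s$cout) * sqrt(2 / fanin),
                   fanin, s$cout),
        b = numeric(s$cout))
    } else if (s$type == "bnorm") {
      l$params <- list(gamma = rep(1, s$dim), beta = numeric(s$dim))
      l$runMean <- numeric(s$dim)
      l$runVar <- rep(1, s$dim)
    } else {
      l$params <- list()
    }
    l$m <- lapply(l$params, function(p) p * 0)
    l$v <- lapply(l$params, function(p) p * 0)
    l
  })
  list(layers = layers, t = 0L)
}

.im2col <- function(X, k) {
  d <- dim(X)                      # n, H, W, C
  oh <- d[2L] - k + 1L; ow <- d[3L] - k + 1L
  cols <- matrix(0, d[1L] * oh * ow, k * k * d[4L])
  idx <- 0L
  for (ky in seq_len(k)) for (kx in seq_len(k)) {
    sl <- X[, ky:(ky + oh - 1L), kx:(kx + ow - 1L), , drop = FALSE]
    cols[, idx * d[4L] + seq_len(d[4L])] <- matrix(sl, ncol = d[4L])
    idx <- idx + 1L
  }
  list(cols = cols, oh = oh, ow = ow)
}

.col2im <- function(dCols, dimX, k, oh, ow) {
  dX <- array(0, dimX)
  C <- dimX[4L]
  idx <- 0L
  for (ky in seq_len(k)) for (kx in seq_len(k)) {
    blk <- array(dCols[, idx * C + seq_len(C)], c(dimX[1L], oh, ow, C))
    dX[, ky:(ky + oh - 1L), kx:(kx + ow - 1L), ] <-
      dX[, ky:(ky + oh - 1L), kx:(kx + ow - 1L), , drop = FALSE] + blk
    idx <- idx + 1L
  }
  dX
}

.nnForward <- function(net, X, train = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "dense") {
      out <- X %*% l$params$W
      out <- sweep(out, 2L, l$params$b, "+")
      caches[[i]] <- list(X = X)
    } else if (l$type == "relu") {
      out <- pmax(X, 0)
      caches[[i]] <- list(X = X)
    } else if (l$type == "lrelu") {
      out <- ifelse(X > 0, X, l$slope * X)
      caches[[i]] <- list(X = X)
    } else if (l$type == "bnorm") {
      if (train) {
        mu <- colMeans(X)
        v <- colMeans(sweep(X, 2L, mu)^2)
        net$layers[[i]]$runMean <- 0.9 * l$runMean + 0.1 * mu
        net$layers[[i]]$runVar <- 0.9 * l$runVar + 0.1 * v
      } else {
        mu <- l$runMean; v <- l$runVar
      }
      invstd <- 1 / sqrt(v + 1e-5)
      xhat <- sweep(sweep(X, 2L, mu), 2L, invstd, "*")
      out <- sweep(sweep(xhat, 2L, l$params$gamma, "*"), 2L, l$params$beta, "+")
      caches[[i]] <- list(xhat = xhat, invstd = invstd)
    } else if (l$type == "conv") {
      ic <- .im2col(X, l$k)
      outM <- sweep(ic$cols %*% l$params$W, 2L, l$params$b, "+")
      out <- array(outM, c(dim(X)[1L], ic$oh, ic$ow, l$cout))
      caches[[i]] <- list(cols = ic$cols, dimX = dim(X), oh = ic$oh,
                          ow = ic$ow)
    } else if (l$type == "pool") {
      d <- dim(X)
      oh <- d[2L] %/% 2L; ow <- d[3L] %/% 2L
      a <- X[, 2L * seq_len(oh) - 1L, 2L * seq_len(ow) - 1L, , drop = FALSE]
      b <- X[, 2L * seq_len(oh) - 1L, 2L * seq_len(ow), , drop = FALSE]
      cc <- X[, 2L * seq_len(oh), 2L * seq_len(ow) - 1L, , drop = FALSE]
      dd <- X[, 2L * seq_len(oh), 2L * seq_len(ow), , drop = FALSE]
      out <- pmax(a, b, cc, dd)
      caches[[i]] <- list(parts = list(a, b, cc, dd), out = out, dimX = d,
                          oh = oh, ow = ow)
    } else if (l$type == "flatten") {
      caches[[i]] <- list(dimX = dim(X))
      out <- matrix(X, nrow = dim(X)[1L])
    } else if (l$type == "l2norm") {
      nrm <- pmax(sqrt(rowSums(X^2)), 1e-12)
      out <- X / nrm
      caches[[i]] <- list(out = out, nrm = nrm)
    } else stop("unknown layer type: ", l$type)
    X <- out
  }
  list(out = X, caches = caches, net = net)
}

.nnBackward <- function(net, caches, dOut) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cache <- caches[[i]]
    if (l$type == "dense") {
      grads[[i]] <- list(W = crossprod(cache$X, dOut), b = colSums(dOut))
      dOut <- dOut %*% t(l$params$W)
    } else if (l$type == "relu") {
      dOut <- dOut * (cache$X > 0)
    } else if (l$type == "lrelu") {
      dOut <- dOut * ifelse(cache$X > 0, 1, l$slope)
    } else if (l$type == "bnorm") {
      xhat <- cache$xhat
      n <- nrow(xhat)
      grads[[i]] <- list(gamma = colSums(dOut * xhat), beta = colSums(dOut))
      dxhat <- sweep(dOut, 2L, l$params$gamma, "*")
      s1 <- colMeans(dxhat)
      s2 <- colMeans(dxhat * xhat)
      dOut <- sweep(sweep(dxhat, 2L, s1) - xhat * rep(s2, each = n),
                    2L, cache$invstd, "*")
    } else if (l$type == "conv") {
      dOutM <- matrix(dOut, ncol = l$cout)
      grads[[i]] <- list(W = crossprod(cache$cols, dOutM), b = colSums(dOutM))
      dCols <- dOutM %*% t(l$params$W)
      dOut <- .col2im(dCols, cache$dimX, l$k, cache$oh, cache$ow)
    } else if (l$type == "pool") {
      d <- cache$dimX
      dX <- array(0, d)
      oh <- cache$oh; ow <- cache$ow
      remaining <- array(TRUE, dim(cache$out))
      offs <- list(c(-1L, -1L), c(-1L, 0L), c(0L, -1L), c(0L, 0L))
      for (j in 1:4) {
        hit <- remaining & (cache$parts[[j]] == cache$out)
        remaining <- remaining & !hit
        ry <- 2L * seq_len(oh) + offs[[j]][1L]
        rx <- 2L * seq_len(ow) + offs[[j]][2L]
        dX[, ry, rx, ] <- dX[, ry, rx, , drop = FALSE] + dOut * hit
      }
      dOut <- dX
    } else if (l$type == "flatten") {
      dOut <- array(dOut, cache$dimX)
    } else if (l$type == "l2norm") {
      e <- cache$out
      dOut <- (dOut - e * rowSums(dOut * e)) / cache$nrm
    }
  }
  list(grads = grads, dIn = dOut)
}

.adamwStep <- function(net, grads, lr, weightDecay = 0.01) {
  net$t <- net$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  bc1 <- 1 - b1^net$t; bc2 <- 1 - b2^net$t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      net$layers[[i]]$m[[nm]] <- b1 * net$layers[[i]]$m[[nm]] + (1 - b1) * g[[nm]]
      net$layers[[i]]$v[[nm]] <- b2 * net$layers[[i]]$v[[nm]] +
        (1 - b2) * g[[nm]]^2
      step <- (net$layers[[i]]$m[[nm]] / bc1) /
        (sqrt(net$layers[[i]]$v[[nm]] / bc2) + eps)
      wd <- if (nm == "W") weightDecay else 0
      net$layers[[i]]$params[[nm]] <- net$layers[[i]]$params[[nm]] -
        lr * (step + wd * net$layers[[i]]$params[[nm]])
    }
  }
  net
}

.netParams <- function(net) lapply(net$layers, function(l)
  c(l$params, l[intersect(names(l), c("runMean", "runVar"))]))

.restoreParams <- function(net, snap) {
  for (i in seq_along(net$layers)) {
    for (nm in names(net$layers[[i]]$params))
      net$layers[[i]]$params[[nm]] <- snap[[i]][[nm]]
    if (!is.null(snap[[i]]$runMean)) {
      net$layers[[i]]$runMean <- snap[[i]]$runMean
      net$layers[[i]]$runVar <- snap[[i]]$runVar
    }
  }
  net
}

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.crossEntropy <- function(p, yIdx) {
  -mean(log(pmax(p[cbind(seq_len(nrow(p)), yIdx)], 1e-12)))
}

# Stratified train/validation split: at least one sample of each class on
# each side when the class has >= 2 samples.
.stratifiedSplit <- function(yIdx, valFrac) {
  val <- integer(0)
  for (cl in unique(yIdx)) {
    idx <- which(yIdx == cl)
    nv <- max(1L, round(length(idx) * valFrac))
    if (nv >= length(idx)) nv <- length(idx) - 1L
    if (nv > 0L) val <- c(val, sample(idx, nv))
  }
  sort(val)
}

# Generic softmax cross-entropy trainer over the layer engine. X is a matrix
# (dense nets) or an n x H x W x C array (conv nets); slicing along the first
# dimension must yield samples.
.nnTrainSoftmax <- function(X, y, spec, classes, lr = 1e-4, epochs = 200L,
                            batch = 64L, patience = 10L, valFrac = 0.2,
                            weightDecay = 0.01, seed = 1L) {
  yIdx <- match(y, classes)
  stopifnot(!anyNA(yIdx))
  net <- .nnInit(spec, seed)           # also seeds the mini-batch stream
  n <- if (is.matrix(X)) nrow(X) else dim(X)[1L]
  take <- function(idx) if (is.matrix(X)) X[idx, , drop = FALSE] else
    X[idx, , , , drop = FALSE]
  val <- .stratifiedSplit(yIdx, valFrac)
  tr <- setdiff(seq_len(n), val)
  Xval <- take(val); yval <- yIdx[val]
  # keep epochs meaningful on small datasets: at least ~4 steps per epoch,
  # otherwise patience-based stopping fires after a handful of optimizer steps
  batch <- min(batch, max(8L, ceiling(length(tr) / 4)))
  best <- Inf; bestSnap <- .netParams(net); wait <- 0L
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample(tr)
    for (b in split(ord, ceiling(seq_along(ord) / batch))) {
      if (length(b) < 2L) next
      fw <- .nnForward(net, take(b), train = TRUE)
      net <- fw$net
      p <- .softmax(fw$out)
      Y <- matrix(0, length(b), length(classes))
      Y[cbind(seq_along(b), yIdx[b])] <- 1
      bw <- .nnBackward(net, fw$caches, (p - Y) / length(b))
      net <- .adamwStep(net, bw$grads, lr, weightDecay)
    }
    pv <- .softmax(.nnForward(net, Xval)$out)
    vloss <- .crossEntropy(pv, yval)
    history <- c(history, vloss)
    if (vloss < best - 1e-6) {
      best <- vloss; bestSnap <- .netParams(net); wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  net <- .restoreParams(net, bestSnap)
  list(net = net, classes = classes, valLoss = best, history = history)
}

.nnPredictSoftmax <- function(model, X) {
  .softmax(.nnForward(model$net, X)$out)
}
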
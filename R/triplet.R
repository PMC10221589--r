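#' Triplet margin loss on squared Euclidean distances
#'
#' Hinge loss forcing an anchor closer to a same-class positive than to a
#' different-class negative by a margin:
#' \code{max(||a - p||^2 - ||a - n||^2 + margin, 0)}.
#'
#' @param a,p,n numeric vectors of equal length (anchor, positive, negative).
#' @param margin positive margin (default 1).
#' @return Non-negative scalar.
#' @examples
#' tripletLoss(c(0, 0), c(0, 0), c(0, 0))        # 1 (both distances zero)
#' tripletLoss(c(0, 0), c(0, 0), c(1, 1))        # 0 (hinge clamps)
#' @export
tripletLoss <- function(a, p, n, margin = 1) {
  if (length(a) != length(p) || length(a) != length(n))
    stop("a, p and n must have equal dimensions")
  max(sum((a - p)^2) - sum((a - n)^2) + margin, 0)
}

#' Configuration for the triplet-loss embedding encoder
#'
#' Three fully connected layers with batch normalization and Leaky ReLU,
#' projecting liver+vessel feature vectors to a 64-dimensional embedding,
#' trained with online (batch-hard) triplet mining under AdamW. The output
#' is L2-normalized, so embeddings live on the unit sphere and the margin is
#' measured on squared chord distances (maximum 4); without this
#' normalization the margin can be satisfied trivially by scale alone and
#' training stalls before the embedding becomes discriminative.
#'
#' @param embeddingDim output dimensionality (default 64).
#' @param hidden widths of the two hidden layers.
#' @param margin triplet margin alpha (> 0, default 1).
#' @param lrSlope negative slope of the Leaky ReLU.
#' @param lr AdamW learning rate.
#' @param epochs epoch cap.
#' @param batch mini-batch size for online mining.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param seed RNG seed controlling init, batching and the validation split.
#' @return Named list of settings.
#' @export
tripletEncoderConfig <- function(embeddingDim = 64L, hidden = c(128L, 96L),
                                 margin = 1, lrSlope = 0.01, lr = 1e-3,
                                 epochs = 150L, batch = 64L, patience = 10L,
                                 seed = 1L) {
  stopifnot(margin > 0, length(hidden) == 2L)
  list(embeddingDim = as.integer(embeddingDim), hidden = as.integer(hidden),
       margin = margin, lrSlope = lrSlope, lr = lr,
       epochs = as.integer(epochs), batch = as.integer(batch),
       patience = as.integer(patience), seed = as.integer(seed))
}

# Batch-hard triplet loss and its gradient w.r.t. the embedding matrix E
# (rows = samples). For each anchor with at least one positive: hardest
# positive = same-class sample at maximal distance, hardest negative =
# other-class sample at minimal distance; hinge on squared distances.
.batchHardTriplet <- function(E, yIdx, margin) {
  n <- nrow(E)
  sq <- rowSums(E^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(E)
  D <- pmax(D, 0)
  same <- outer(yIdx, yIdx, "==")
  diag(same) <- NA                      # exclude self as positive
  losses <- numeric(n)
  dE <- matrix(0, n, ncol(E))
  used <- 0L
  for (a in seq_len(n)) {
    pos <- which(!is.na(same[a, ]) & same[a, ])
    neg <- which(!is.na(same[a, ]) & !same[a, ])
    if (!length(pos) || !length(neg)) next
    p <- pos[which.max(D[a, pos])]
    ng <- neg[which.min(D[a, neg])]
    used <- used + 1L
    l <- D[a, p] - D[a, ng] + margin
    if (l > 0) {
      losses[a] <- l
      dE[a, ] <- dE[a, ] + 2 * (E[ng, ] - E[p, ])
      dE[p, ] <- dE[p, ] + 2 * (E[p, ] - E[a, ])
      dE[ng, ] <- dE[ng, ] + 2 * (E[a, ] - E[ng, ])
    }
  }
  if (!used) return(list(loss = 0, grad = dE))
  list(loss = sum(losses) / used, grad = dE / used)
}

#' Train the triplet-loss embedding encoder on clear data
#'
#' Fits the 3-layer encoder of [tripletEncoderConfig()] with online
#' batch-hard triplet mining: within each mini-batch every sample acts as an
#' anchor paired with its hardest positive and hardest negative. Training
#' stops when the validation triplet loss has not improved for
#' \code{patience} epochs; the best weights are restored. Deterministic for a
#' fixed seed.
#'
#' @param X numeric n x d matrix of input feature vectors.
#' @param labels character vector of class labels, length n; every class must
#'   have at least 2 samples.
#' @param config a [tripletEncoderConfig()].
#' @return An encoder object (list) for [encodeFeatures()], carrying the
#'   training-loss history in \code{$history}.
#' @export
trainTripletEncoder <- function(X, labels, config = tripletEncoderConfig()) {
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop("need at least 2 classes to form triplets")
  cnt <- table(labels)
  if (any(cnt < 2L))
    stop("every class needs >= 2 samples; offending: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  yIdx <- match(labels, classes)
  ctr <- colMeans(X)
  scl <- pmax(apply(X, 2L, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  spec <- list(
    list(type = "dense", nin = ncol(X), nout = config$hidden[1L]),
    list(type = "bnorm", dim = config$hidden[1L]),
    list(type = "lrelu", slope = config$lrSlope),
    list(type = "dense", nin = config$hidden[1L], nout = config$hidden[2L]),
    list(type = "bnorm", dim = config$hidden[2L]),
    list(type = "lrelu", slope = config$lrSlope),
    list(type = "dense", nin = config$hidden[2L],
         nout = config$embeddingDim),
    list(type = "l2norm"))
  net <- .nnInit(spec, config$seed)
  val <- .stratifiedSplit(yIdx, 0.2)
  tr <- setdiff(seq_len(nrow(Xs)), val)
  # same small-data batch rule as the classifier heads: >= ~4 steps/epoch
  batchSize <- min(config$batch, max(8L, ceiling(length(tr) / 4)))
  best <- Inf; bestSnap <- .netParams(net); wait <- 0L
  history <- numeric(0)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr)
    epochLoss <- c()
    for (b in split(ord, ceiling(seq_along(ord) / batchSize))) {
      if (length(b) < 4L) next
      fw <- .nnForward(net, Xs[b, , drop = FALSE], train = TRUE)
      net <- fw$net
      bh <- .batchHardTriplet(fw$out, yIdx[b], config$margin)
      epochLoss <- c(epochLoss, bh$loss)
      bw <- .nnBackward(net, fw$caches, bh$grad)
      net <- .adamwStep(net, bw$grads, config$lr)
    }
    Ev <- .nnForward(net, Xs[val, , drop = FALSE])$out
    vloss <- .batchHardTriplet(Ev, yIdx[val], config$margin)$loss
    history <- c(history, mean(epochLoss))
    if (vloss < best - 1e-6) {
      best <- vloss; bestSnap <- .netParams(net); wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  net <- .restoreParams(net, bestSnap)
  list(net = net, center = ctr, scale = scl, config = config,
       history = history, valLoss = best, kind = "triplet_encoder")
}

#' Embed feature vectors with a trained triplet encoder
#'
#' @param encoder result of [trainTripletEncoder()].
#' @param X numeric n x d matrix (same feature layout as at training time).
#' @return Numeric n x embeddingDim matrix.
#' @export
encodeFeatures <- function(encoder, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  Xs <- sweep(sweep(X, 2L, encoder$center), 2L, encoder$scale, "/")
  .nnForward(encoder$net, Xs)$out
}
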
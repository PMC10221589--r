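# Model-level wrappers: a two-fully-connected-layer MLP head with
# cross-entropy loss (the classifier used at every hierarchy level) and a
# small convolutional image classifier for the vessel-image group. Inputs to
# the MLP are z-scored with statistics frozen from the training set.

.mlpTrain <- function(X, y, classes, hidden = 256L, lr = 1e-4, epochs = 200L,
                      batch = 64L, patience = 10L, weightDecay = 0.01,
                      seed = 1L) {
  ctr <- colMeans(X)
  scl <- pmax(apply(X, 2L, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  spec <- list(
    list(type = "dense", nin = ncol(X), nout = hidden),
    list(type = "relu"),
    list(type = "dense", nin = hidden, nout = length(classes)))
  fit <- .nnTrainSoftmax(Xs, y, spec, classes, lr = lr, epochs = epochs,
                         batch = batch, patience = patience,
                         weightDecay = weightDecay, seed = seed)
  c(fit, list(center = ctr, scale = scl, kind = "mlp"))
}

.mlpPredict <- function(model, X, prob = FALSE) {
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  p <- .nnPredictSoftmax(model, Xs)
  if (prob) return(p)
  model$classes[max.col(p, ties.method = "first")]
}

# Small CNN over side x side x 3 inputs: two conv/pool stages and a dense
# head. Desk-scale stand-in for a large pretrained backbone; any callable
# backbone can replace it through the group2 config.
.cnnSpec <- function(side, classes, filters = c(8L, 16L), dense = 64L) {
  s1 <- (side - 2L) %/% 2L               # conv3 valid + pool2
  s2 <- (s1 - 2L) %/% 2L
  list(
    list(type = "conv", k = 3L, cin = 3L, cout = filters[1L]),
    list(type = "relu"),
    list(type = "pool"),
    list(type = "conv", k = 3L, cin = filters[1L], cout = filters[2L]),
    list(type = "relu"),
    list(type = "pool"),
    list(type = "flatten"),
    list(type = "dense", nin = s2 * s2 * filters[2L], nout = dense),
    list(type = "relu"),
    list(type = "dense", nin = dense, nout = length(classes)))
}

.cnnTrain <- function(X, y, classes, side, lr = 1e-3, epochs = 60L,
                      batch = 32L, patience = 10L, seed = 1L) {
  spec <- .cnnSpec(side, classes)
  fit <- .nnTrainSoftmax(X, y, spec, classes, lr = lr, epochs = epochs,
                         batch = batch, patience = patience, seed = seed)
  c(fit, list(side = side, kind = "cnn"))
}

.cnnPredict <- function(model, X, prob = FALSE) {
  p <- .nnPredictSoftmax(model, X)
  if (prob) return(p)
  model$classes[max.col(p, ties.method = "first")]
}
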
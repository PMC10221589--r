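# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized implementations: explicit loops and the
# closed-form 2x2 eigendecomposition.

randomMask <- function(H = 12L, W = 16L, p = 0.3) {
  n <- max(1L, stats::rbinom(1L, H * W, p))
  idx <- sample(H * W, n)
  BinaryMask(cbind(x = (idx - 1L) %/% H, y = (idx - 1L) %% H),
             width = W, height = H)
}

oracleCentroid <- function(mask) {
  cc <- maskCoords(mask)
  sx <- 0; sy <- 0
  for (i in seq_len(nrow(cc))) {
    sx <- sx + cc[i, 1L]
    sy <- sy + cc[i, 2L]
  }
  as.numeric(c(sx, sy)) / nrow(cc)
}

# closed-form eigendecomposition of the 2x2 population covariance
oracleMorphology <- function(mask) {
  cc <- maskCoords(mask)
  n <- nrow(cc)
  mx <- sum(cc[, 1L]) / n
  my <- sum(cc[, 2L]) / n
  sxx <- 0; syy <- 0; sxy <- 0
  for (i in seq_len(n)) {
    dx <- cc[i, 1L] - mx; dy <- cc[i, 2L] - my
    sxx <- sxx + dx * dx; syy <- syy + dy * dy; sxy <- sxy + dx * dy
  }
  sxx <- sxx / n; syy <- syy / n; sxy <- sxy / n
  tr <- sxx + syy
  disc <- sqrt(max((sxx - syy)^2 / 4 + sxy^2, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l1 - l2 <= 1e-12 * max(l1, 1)) return(c(l1, l2, 1, 0, 0, 1))
  v1 <- if (abs(sxy) > 1e-300) c(l1 - syy, sxy) else
    if (sxx >= syy) c(1, 0) else c(0, 1)
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(-v1[2L], v1[1L])
  fix <- function(v) {
    j <- if (abs(abs(v[1L]) - abs(v[2L])) <= 1e-12) 1L else which.max(abs(v))
    if (v[j] < 0) -v else v
  }
  as.numeric(c(l1, max(l2, 0), fix(v1), fix(v2)))
}

oracleArgmaxMap <- function(logits) {
  d <- dim(logits)
  out <- matrix(0L, d[2L], d[3L])
  for (h in seq_len(d[2L])) for (w in seq_len(d[3L])) {
    best <- 1L
    for (n in seq_len(d[1L])) if (logits[n, h, w] > logits[best, h, w])
      best <- n
    out[h, w] <- best - 1L
  }
  out
}

oracleScore <- function(truth, predicted, classes) {
  out <- data.frame()
  for (cl in classes) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    if (tp + fn == 0) next
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- tp / (tp + fn)
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    out <- rbind(out, data.frame(class = cl, precision = p, recall = r,
                                 f1 = f))
  }
  out
}

# small, quick spec set shared by pipeline-level unit tests
testSpecs <- function(overlap = 0) {
  defaultScanSpecs(overlap = overlap, H = 64L, W = 64L, cF = 16L, cQ = 16L,
                   seed = 202L)
}

testSubjects <- paste0("t", 1:4)

# fast hierarchy configuration for unit tests (not the study conditions)
testConfig <- function(seed = 1L) {
  hierarchyConfig(seed = seed, hidden = 64L, epochs = 400L,
                  group2Epochs = 25L, side = 24L,
                  triplet = tripletEncoderConfig(hidden = c(64L, 48L),
                                                 epochs = 80L, seed = seed))
}
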
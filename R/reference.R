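#' Select grid-sampled reference points from clear-data embeddings
#'
#' Computes a 2-d t-SNE projection of the embeddings, lays a uniform
#' rows x cols grid (default 10 x 10) over the projection's axis-aligned
#' bounding box, and uniformly samples exactly one point from every occupied
#' cell. The selected points are retained with their original
#' full-dimensional embeddings and labels for k-nearest-neighbour voting.
#' Cells are half-open on their right/top edges except the last row/column,
#' which is closed so boundary points fall inside the grid.
#'
#' @param embeddings numeric n x d matrix (n >= 1) of clear-data embeddings.
#' @param labels character vector of class labels, length n.
#' @param gridRows,gridCols grid dimensions (default 10 x 10).
#' @param seed RNG seed for t-SNE and within-cell sampling.
#' @param perplexity t-SNE perplexity (default 30); automatically reduced
#'   with a warning when the input is too small to support it.
#' @return A [ReferenceSet-class].
#' @export
selectReferencePoints <- function(embeddings, labels, gridRows = 10L,
                                  gridCols = 10L, seed = 1L,
                                  perplexity = 30) {
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, nrow = 1L)
  n <- nrow(embeddings)
  stopifnot(n >= 1L, length(labels) == n)
  set.seed(seed)
  if (n >= 4L) {
    maxPerp <- floor((n - 1) / 3)
    if (perplexity > maxPerp) {
      warning(sprintf(
        "perplexity %g too large for %d points; reduced to %d",
        perplexity, n, maxPerp))
      perplexity <- maxPerp
    }
    Y <- Rtsne::Rtsne(embeddings, dims = 2L, perplexity = perplexity,
                      theta = if (n < 2000L) 0 else 0.5,
                      check_duplicates = FALSE, pca = TRUE,
                      max_iter = 500L, num_threads = 1L)$Y
  } else {
    # too few points for t-SNE: any layout yields the same one-per-cell
    # selection, so place the points on a line
    Y <- cbind(seq_len(n), 0)
  }
  bounds <- c(range(Y[, 1L]), range(Y[, 2L]))
  cells <- tsneGridCells(Y, gridRows, gridCols, bounds)
  key <- paste(cells[, 1L], cells[, 2L], sep = "_")
  pick <- vapply(split(seq_len(n), key), function(idx)
    if (length(idx) == 1L) idx else sample(idx, 1L), integer(1L))
  pick <- unname(pick[order(names(pick))])
  new("ReferenceSet",
      embeddings = embeddings[pick, , drop = FALSE],
      labels = as.character(labels[pick]),
      tsne = Y[pick, , drop = FALSE],
      cells = cells[pick, , drop = FALSE],
      gridDim = c(as.integer(gridRows), as.integer(gridCols)),
      bounds = bounds, seed = as.integer(seed))
}

#' Assign 2-d points to uniform grid cells over a bounding box
#'
#' @param Y numeric n x 2 matrix of 2-d coordinates.
#' @param gridRows,gridCols grid dimensions.
#' @param bounds numeric length-4 (xmin, xmax, ymin, ymax).
#' @return Integer n x 2 matrix of 1-based (row, col) cell indices; rows index
#'   the y axis, columns the x axis.
#' @export
tsneGridCells <- function(Y, gridRows, gridCols, bounds) {
  bin <- function(v, lo, hi, k) {
    span <- hi - lo
    if (span <= 0) return(rep(1L, length(v)))
    pmin(floor((v - lo) / span * k), k - 1L) + 1L
  }
  cbind(row = bin(Y[, 2L], bounds[3L], bounds[4L], gridRows),
        col = bin(Y[, 1L], bounds[1L], bounds[2L], gridCols))
}

#' @describeIn selectReferencePoints reference embeddings (m x d matrix)
#' @param x a \code{ReferenceSet}
#' @export
refEmbeddings <- function(x) x@embeddings

#' @describeIn selectReferencePoints reference labels
#' @export
refLabels <- function(x) x@labels

#' @describeIn selectReferencePoints (row, col) grid-cell index per reference
#' @export
refCells <- function(x) x@cells

#' @describeIn selectReferencePoints t-SNE coordinates of the references
#' @export
refTsne <- function(x) x@tsne

#' @describeIn selectReferencePoints grid dimensions and bounding box
#' @export
refGrid <- function(x) list(dim = x@gridDim, bounds = x@bounds)

setMethod("show", "ReferenceSet", function(object) {
  cat(sprintf("ReferenceSet: %d references on a %dx%d grid (%d-d embeddings)\n",
              nrow(object@embeddings), object@gridDim[1L], object@gridDim[2L],
              ncol(object@embeddings)))
  print(table(object@labels))
})

#' Classify embeddings by KNN vote over reference points
#'
#' Majority label among the k Euclidean-nearest reference points in the full
#' embedding space (k = 3 by default). Vote ties are broken by the label of
#' the single nearest neighbour; distance ties are broken by reference
#' insertion order.
#'
#' @param query numeric vector (one embedding) or n x d matrix.
#' @param refs a [ReferenceSet-class] with at least k entries.
#' @param k number of neighbours (default 3).
#' @return Character vector of predicted labels.
#' @export
knnClassify <- function(query, refs, k = 3L) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  R <- refs@embeddings
  if (nrow(R) < k) stop(sprintf("need at least k = %d references, have %d",
                                k, nrow(R)))
  vapply(seq_len(nrow(query)), function(i) {
    d <- colSums((t(R) - query[i, ])^2)
    nb <- order(d, seq_along(d))[seq_len(k)]   # stable under distance ties
    votes <- table(refs@labels[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) top else refs@labels[nb[1L]]
  }, character(1L))
}

#' Serialize / load a ReferenceSet as HDF5
#'
#' Stores embeddings, labels, t-SNE coordinates, cell indices, grid metadata
#' and the seed; a summary CSV (label, cell, t-SNE coordinates) is written
#' alongside when \code{csv = TRUE}.
#'
#' @param refs a [ReferenceSet-class].
#' @param path output .h5 path.
#' @param csv also write \code{paste0(path, ".csv")} for inspection.
#' @return \code{readReferenceSet}: the restored ReferenceSet.
#' @export
writeReferenceSet <- function(refs, path, csv = FALSE) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(refs@embeddings, path, "embeddings")
  rhdf5::h5write(refs@labels, path, "labels")
  rhdf5::h5write(refs@tsne, path, "tsne")
  rhdf5::h5write(refs@cells, path, "cells")
  rhdf5::h5write(refs@gridDim, path, "grid_dim")
  rhdf5::h5write(refs@bounds, path, "bounds")
  rhdf5::h5write(refs@seed, path, "seed")
  if (csv)
    utils::write.csv(data.frame(
      label = refs@labels, cell_row = refs@cells[, 1L],
      cell_col = refs@cells[, 2L], tsne_x = refs@tsne[, 1L],
      tsne_y = refs@tsne[, 2L]), paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname writeReferenceSet
#' @export
readReferenceSet <- function(path) {
  rd <- function(nm) rhdf5::h5read(path, nm)
  cells <- rd("cells"); storage.mode(cells) <- "integer"
  new("ReferenceSet", embeddings = rd("embeddings"),
      labels = as.character(rd("labels")), tsne = rd("tsne"), cells = cells,
      gridDim = as.integer(rd("grid_dim")), bounds = as.numeric(rd("bounds")),
      seed = as.integer(rd("seed")))
}
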
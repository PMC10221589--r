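#' Global average pooling of an encoder feature map
#'
#' Per-channel spatial mean: element i is the arithmetic mean of channel i of
#' the C_F x H_F x W_F feature map.
#'
#' @param featureMap numeric C_F x H_F x W_F array with H_F, W_F >= 1.
#' @return Numeric vector of length C_F.
#' @examples
#' globalAveragePool(array(5, c(3, 2, 2)))  # c(5, 5, 5)
#' @export
globalAveragePool <- function(featureMap) {
  d <- dim(featureMap)
  if (is.null(d) || length(d) != 3L || d[2L] < 1L || d[3L] < 1L || !length(featureMap))
    stop("featureMap must be a C_F x H_F x W_F array with non-empty spatial extent")
  rowMeans(matrix(featureMap, nrow = d[1L]))
}

#' Detection tag of a class mask
#'
#' 1 if the class is detected (mask non-empty), 0 otherwise.
#'
#' @param mask a [BinaryMask-class].
#' @return 0 or 1.
#' @export
classTag <- function(mask) as.numeric(nrow(mask@coords) > 0L)

#' Centroid of a class mask
#'
#' Mean of member-pixel x and y coordinates, in raw pixel units (0-based,
#' x = column, y = row).
#'
#' @param mask a non-empty [BinaryMask-class].
#' @return Numeric length-2 vector (L_x, L_y).
#' @export
maskCentroid <- function(mask) {
  if (!nrow(mask@coords)) stop("centroid undefined for an empty mask")
  colMeans(mask@coords)
}

#' Area fraction of a class mask
#'
#' Member-pixel count divided by the raster area H*W. Empty masks give 0.
#'
#' @param mask a [BinaryMask-class].
#' @return Numeric scalar in [0, 1].
#' @export
sizeFraction <- function(mask) {
  nrow(mask@coords) / (as.numeric(mask@height) * as.numeric(mask@width))
}

#' Morphology descriptor of a class mask
#'
#' Eigenvalues (descending) and unit eigenvectors of the 2x2 covariance matrix
#' of member-pixel (x, y) coordinates, population-normalized (1/n), flattened
#' as [lambda1, lambda2, v1x, v1y, v2x, v2y]. Eigenvector signs are fixed by
#' making the largest-magnitude component positive (first component on ties).
#' When the two eigenvalues coincide (including single-pixel masks) the
#' eigenbasis is not unique and the canonical basis (1,0), (0,1) is returned.
#'
#' @param mask a non-empty [BinaryMask-class].
#' @return Numeric vector of length 6.
#' @examples
#' m <- BinaryMask(cbind(0:4, rep(0L, 5)), width = 5L, height = 1L)
#' maskMorphology(m)  # lambda2 = 0, v1 = (1, 0)
#' @export
maskMorphology <- function(mask) {
  cc <- mask@coords
  n <- nrow(cc)
  if (!n) stop("morphology undefined for an empty mask")
  ctr <- sweep(cc, 2L, colMeans(cc))
  S <- crossprod(ctr) / n
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  if (lam[1L] - lam[2L] <= 1e-12 * max(lam[1L], 1)) {
    vecs <- diag(2)
  } else {
    vecs <- apply(e$vectors, 2L, .fixSign)
  }
  c(lam[1L], lam[2L], vecs[, 1L], vecs[, 2L])
}

.fixSign <- function(v) {
  j <- if (abs(abs(v[1L]) - abs(v[2L])) <= 1e-12) 1L else which.max(abs(v))
  if (v[j] < 0) -v else v
}

#' Per-class geometric feature matrix
#'
#' The (N-1) x 10 matrix with one row per non-background class:
#' [T, L_x, L_y, S, lambda1, lambda2, v1x, v1y, v2x, v2y]. Rows of undetected
#' classes are all zeros. With \code{normalize = TRUE} centroids are divided
#' by (W, H) and eigenvalues by W*H; the default reports raw pixel units.
#'
#' @param classMap integer H x W matrix with values in [0, N-1].
#' @param nClasses number of classes N including background.
#' @param normalize scale centroids and eigenvalues by the image extent
#'   (default FALSE).
#' @return A [GeometricFeatures-class] whose \code{V} slot is (N-1) x 10.
#' @export
geometricFeatureMatrix <- function(classMap, nClasses, normalize = FALSE) {
  masks <- binaryMasks(classMap, nClasses)
  H <- nrow(classMap); W <- ncol(classMap)
  V <- t(vapply(masks, function(m) {
    if (!nrow(m@coords)) return(numeric(10L))
    c(1, maskCentroid(m), sizeFraction(m), maskMorphology(m))
  }, numeric(10L)))
  if (normalize) {
    V[, 2L] <- V[, 2L] / W
    V[, 3L] <- V[, 3L] / H
    V[, 5:6] <- V[, 5:6] / (W * H)
  }
  colnames(V) <- c("tag", "loc_x", "loc_y", "size",
                   "lambda1", "lambda2", "v1x", "v1y", "v2x", "v2y")
  new("GeometricFeatures", V = V)
}

#' @describeIn geometricFeatureMatrix extract the raw (N-1) x 10 matrix
#' @param x a \code{GeometricFeatures}
#' @export
geometryMatrix <- function(x) x@V

setMethod("show", "GeometricFeatures", function(object) {
  cat(sprintf("GeometricFeatures: %d classes x 10 descriptors (%d detected)\n",
              nrow(object@V), sum(object@V[, 1L])))
})

#' Assemble the classifier input vector from artifact components
#'
#' Concatenates, in fixed order, the requested feature segments of an
#' artifact: \code{gap} (global-average-pooled feature map, length C_F),
#' \code{queries} (flattened query embeddings, C_Q*N), \code{class_scores}
#' (N*(N+1)) and \code{geometric} (flattened geometric feature matrix, 10 per
#' selected class). Segment lengths are recorded in the result's layout so
#' offsets can be recovered. Sub-classifiers that consume only a subset of
#' features (e.g. liver-only geometry) request fewer parts or restrict
#' \code{geomClasses}.
#'
#' @param artifact a [SegmentationArtifact-class].
#' @param parts character subset of
#'   \code{c("gap", "queries", "class_scores", "geometric")}.
#' @param geomClasses optional integer vector of class indices (1..N-1) to
#'   which the geometric segment is restricted; default all.
#' @param normalize passed to [geometricFeatureMatrix()].
#' @return A [FeatureVector-class].
#' @export
assembleFeatureVector <- function(artifact,
                                  parts = c("gap", "queries", "class_scores",
                                            "geometric"),
                                  geomClasses = NULL, normalize = FALSE) {
  known <- c("gap", "queries", "class_scores", "geometric")
  parts <- known[known %in% parts]           # fixed canonical order
  if (!length(parts)) stop("no feature parts requested")
  segs <- list()
  for (p in parts) {
    segs[[p]] <- switch(p,
      gap = {
        if (is.null(artifact@featureMap))
          stop("requested part 'gap' but the artifact has no feature_map")
        globalAveragePool(artifact@featureMap)
      },
      queries = {
        if (is.null(artifact@queryEmbeddings))
          stop("requested part 'queries' but the artifact has no query_embeddings")
        as.numeric(artifact@queryEmbeddings)
      },
      class_scores = {
        if (is.null(artifact@classScores))
          stop("requested part 'class_scores' but the artifact has no class_scores")
        as.numeric(artifact@classScores)
      },
      geometric = {
        V <- geometryMatrix(geometricFeatureMatrix(
          artifact@classMap, artifact@nClasses, normalize = normalize))
        if (!is.null(geomClasses)) V <- V[geomClasses, , drop = FALSE]
        as.numeric(t(V))                     # class-major flattening
      })
  }
  layout <- vapply(segs, length, integer(1L))
  new("FeatureVector", values = unlist(segs, use.names = FALSE),
      layout = layout)
}

#' @describeIn assembleFeatureVector numeric values of a FeatureVector
#' @param x a \code{FeatureVector}
#' @export
featureValues <- function(x) x@values

#' @describeIn assembleFeatureVector named segment lengths, in order
#' @export
featureLayout <- function(x) x@layout

#' @describeIn assembleFeatureVector 0-based starting offset of each segment
#' @export
featureOffsets <- function(x) {
  off <- cumsum(c(0L, unname(x@layout)))
  stats::setNames(off[-length(off)], names(x@layout))
}

setMethod("show", "FeatureVector", function(object) {
  cat(sprintf("FeatureVector: length %d (%s)\n", length(object@values),
              paste(sprintf("%s=%d", names(object@layout), object@layout),
                    collapse = ", ")))
})

#' Export a batch of feature vectors to CSV with a JSON layout sidecar
#'
#' @param vectors list of [FeatureVector-class] with identical layouts.
#' @param ids character vector of row identifiers.
#' @param path output CSV path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @return The CSV path, invisibly.
#' @export
exportFeatureCSV <- function(vectors, ids, path) {
  stopifnot(length(vectors) == length(ids), length(vectors) > 0L)
  lay <- featureLayout(vectors[[1L]])
  cols <- unlist(lapply(names(lay), function(nm)
    sprintf("%s_%03d", nm, seq_len(lay[[nm]]))))
  M <- do.call(rbind, lapply(vectors, featureValues))
  df <- data.frame(id = ids, M)
  names(df) <- c("id", cols)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(layout = as.list(lay)), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}
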
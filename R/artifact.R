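#' Construct a validated SegmentationArtifact
#'
#' @param image numeric H x W matrix of grayscale intensities (0-255).
#' @param classMap integer H x W matrix of hard class labels, 0 = background.
#' @param maskLogits optional numeric N x H x W array of pre-activation mask
#'   predictions.
#' @param queryEmbeddings optional numeric C_Q x N matrix of per-segment
#'   embeddings, one column per query/class.
#' @param featureMap optional numeric C_F x H_F x W_F encoder feature map.
#' @param classScores optional numeric N x (N+1) matrix of raw per-query class
#'   scores (last column = no-object).
#' @param nClasses number of classes N including background.
#' @param subjectId subject identifier string.
#' @param label scan-location code or NA.
#' @return A validated [SegmentationArtifact-class] object.
#' @examples
#' a <- SegmentationArtifact(
#'   image = matrix(0, 4, 4),
#'   classMap = matrix(0L, 4, 4),
#'   maskLogits = array(0, c(2, 4, 4)),
#'   nClasses = 2L, subjectId = "s1")
#' nClasses(a)
#' @export
SegmentationArtifact <- function(image, classMap, maskLogits = NULL,
                                 queryEmbeddings = NULL, featureMap = NULL,
                                 classScores = NULL, nClasses,
                                 subjectId = "unknown", label = NA_character_) {
  storage.mode(classMap) <- "integer"
  new("SegmentationArtifact",
      image = image, classMap = classMap, maskLogits = maskLogits,
      queryEmbeddings = queryEmbeddings, featureMap = featureMap,
      classScores = classScores, nClasses = as.integer(nClasses),
      subjectId = as.character(subjectId), label = as.character(label))
}

#' @describeIn SegmentationArtifact-class grayscale image matrix
#' @param object,x a \code{SegmentationArtifact}
#' @export
scanImage <- function(x) x@image

#' @describeIn SegmentationArtifact-class hard class-label map
#' @export
classMap <- function(x) x@classMap

#' @describeIn SegmentationArtifact-class pre-activation mask predictions
#' @export
maskLogits <- function(x) x@maskLogits

#' @describeIn SegmentationArtifact-class per-segment query embeddings
#' @export
queryEmbeddings <- function(x) x@queryEmbeddings

#' @describeIn SegmentationArtifact-class encoder/FPN feature map
#' @export
featureMap <- function(x) x@featureMap

#' @describeIn SegmentationArtifact-class raw per-query class scores
#' @export
classScores <- function(x) x@classScores

#' @describeIn SegmentationArtifact-class number of classes incl. background
#' @export
nClasses <- function(x) x@nClasses

#' @describeIn SegmentationArtifact-class subject identifier
#' @export
subjectId <- function(x) x@subjectId

#' @describeIn SegmentationArtifact-class scan-location label (NA if absent)
#' @export
scanLabel <- function(x) x@label

setMethod("show", "SegmentationArtifact", function(object) {
  d <- dim(object@image)
  cat(sprintf("SegmentationArtifact %dx%d, N=%d classes\n",
              d[1L], d[2L], object@nClasses))
  cat(sprintf("  subject: %s  label: %s\n", object@subjectId, object@label))
  present <- c(
    mask_logits = !is.null(object@maskLogits),
    query_embeddings = !is.null(object@queryEmbeddings),
    feature_map = !is.null(object@featureMap),
    class_scores = !is.null(object@classScores))
  cat("  tensors:", paste(names(present)[present], collapse = ", "),
      if (!all(present)) paste0("(absent: ",
        paste(names(present)[!present], collapse = ", "), ")"), "\n")
  det <- sort(unique(as.integer(object@classMap)))
  cat("  classes in map:", paste(det, collapse = ", "), "\n")
})

#' Construct a BinaryMask from 0-based pixel coordinates
#'
#' @param coords integer n x 2 matrix of 0-based (x, y) pixel coordinates
#'   (x = column, y = row, origin top-left).
#' @param width,height raster extent.
#' @return A validated [BinaryMask-class].
#' @examples
#' m <- BinaryMask(cbind(x = c(0L, 2L), y = c(0L, 0L)), width = 4L, height = 4L)
#' maskCentroid(m)
#' @export
BinaryMask <- function(coords, width, height) {
  coords <- matrix(as.integer(coords), ncol = 2L,
                   dimnames = list(NULL, c("x", "y")))
  new("BinaryMask", coords = coords, width = as.integer(width),
      height = as.integer(height))
}

#' @describeIn BinaryMask-class 0-based (x, y) member-pixel coordinates
#' @param x a \code{BinaryMask}
#' @export
maskCoords <- function(x) x@coords

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d px on %dx%d raster\n",
              nrow(object@coords), object@height, object@width))
})

#' Collapse soft mask predictions into a hard class map
#'
#' Takes the per-pixel argmax along the class dimension of the mask-prediction
#' tensor. Ties are broken toward the lowest class index.
#'
#' @param maskLogits numeric N x H x W array, N >= 2.
#' @return Integer H x W matrix with values in [0, N-1].
#' @examples
#' lg <- array(0, c(2, 2, 2)); lg[2, , ] <- 1
#' classMapFromLogits(lg)  # all 1
#' @export
classMapFromLogits <- function(maskLogits) {
  d <- dim(maskLogits)
  if (is.null(d) || length(d) != 3L || any(d == 0L))
    stop("maskLogits must be a non-empty N x H x W array")
  if (d[1L] < 2L) stop("need at least 2 classes (N >= 2)")
  flat <- matrix(maskLogits, nrow = d[1L])        # N x (H*W), pixels in cols
  idx <- max.col(t(flat), ties.method = "first") - 1L
  matrix(as.integer(idx), nrow = d[2L], ncol = d[3L])
}

#' Split a class map into per-class binary masks
#'
#' Returns one [BinaryMask-class] per non-background class (1..N-1); the
#' background class produces no mask. The masks partition the non-background
#' pixels.
#'
#' @param classMap integer H x W matrix with values in [0, N-1].
#' @param nClasses number of classes N including background.
#' @return List of N-1 BinaryMask objects; element i is the mask of class i.
#' @examples
#' cm <- matrix(0L, 3, 3); cm[2, 2] <- 2L
#' lengths(lapply(binaryMasks(cm, 4L), maskCoords)) / 2
#' @export
binaryMasks <- function(classMap, nClasses) {
  nClasses <- as.integer(nClasses)
  if (length(classMap) && max(classMap) >= nClasses)
    stop(sprintf("classMap contains label %d >= nClasses %d",
                 max(classMap), nClasses))
  H <- nrow(classMap); W <- ncol(classMap)
  lapply(seq_len(nClasses - 1L), function(i) {
    rc <- which(classMap == i, arr.ind = TRUE)
    BinaryMask(cbind(x = rc[, 2L] - 1L, y = rc[, 1L] - 1L),
               width = W, height = H)
  })
}

#' Rebuild a dense logical raster from a BinaryMask
#'
#' @param mask a [BinaryMask-class].
#' @return Logical H x W matrix.
#' @export
maskToLogical <- function(mask) {
  out <- matrix(FALSE, mask@height, mask@width)
  cc <- mask@coords
  if (nrow(cc)) out[cbind(cc[, 2L] + 1L, cc[, 1L] + 1L)] <- TRUE
  out
}
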
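#' @import methods
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' SegmentationArtifact: per-image outputs of a segmentation backend
#'
#' Container for everything a (real or simulated) transformer-decoder
#' segmentation model emits for one ultrasound frame: the grayscale image, the
#' hard class-label map, per-class pre-activation mask predictions, per-segment
#' query embeddings, the encoder/FPN feature map and per-query class scores.
#' Background is always class index 0; organ/vessel classes are 1..N-1.
#'
#' @slot image numeric H x W matrix, intensities in [0, 255].
#' @slot classMap integer H x W matrix with values in [0, N-1]; 0 = background.
#' @slot maskLogits numeric array N x H x W of pre-activation mask predictions,
#'   or NULL when the backend did not provide them.
#' @slot queryEmbeddings numeric C_Q x N matrix of per-segment embeddings
#'   (one column per query/class), or NULL.
#' @slot featureMap numeric array C_F x H_F x W_F (encoder/FPN output), or NULL.
#' @slot classScores numeric N x (N+1) matrix of raw per-query class scores
#'   (last column = no-object), or NULL. Stored unnormalized.
#' @slot nClasses integer, N including background.
#' @slot subjectId character scalar identifying the imaged subject.
#' @slot label character scalar scan-location code, or NA when unlabeled.
#'
#' @seealso [SegmentationArtifact()] for construction with validation,
#'   [readArtifact()] / [writeArtifact()] for HDF5 round trips.
#' @exportClass SegmentationArtifact
setClass("SegmentationArtifact",
  slots = c(
    image = "matrix",
    classMap = "matrix",
    maskLogits = "arrayOrNULL",
    queryEmbeddings = "matrixOrNULL",
    featureMap = "arrayOrNULL",
    classScores = "matrixOrNULL",
    nClasses = "integer",
    subjectId = "character",
    label = "character"
  )
)

setValidity("SegmentationArtifact", function(object) {
  msgs <- character()
  n <- object@nClasses
  dimg <- dim(object@image)
  dmap <- dim(object@classMap)
  if (length(n) != 1L || is.na(n) || n < 2L)
    msgs <- c(msgs, "nClasses must be a single integer >= 2")
  if (!identical(dimg, dmap))
    msgs <- c(msgs, sprintf(
      "class_map dimensions (%s) do not match image dimensions (%s)",
      paste(dmap, collapse = "x"), paste(dimg, collapse = "x")))
  cm <- object@classMap
  if (length(cm) && (min(cm) < 0L || max(cm) > n - 1L))
    msgs <- c(msgs, sprintf("classMap values must lie in [0, %d]", n - 1L))
  if (!is.null(object@maskLogits)) {
    dl <- dim(object@maskLogits)
    if (length(dl) != 3L || dl[1L] != n || !identical(dl[2:3], dimg))
      msgs <- c(msgs, sprintf(
        "maskLogits must be %d x %s, got %s", n,
        paste(dimg, collapse = " x "), paste(dl, collapse = " x ")))
  }
  if (!is.null(object@queryEmbeddings) && ncol(object@queryEmbeddings) != n)
    msgs <- c(msgs, sprintf(
      "queryEmbeddings must have exactly %d columns (one per query/class)", n))
  if (!is.null(object@classScores)) {
    ds <- dim(object@classScores)
    if (ds[1L] != n || ds[2L] != n + 1L)
      msgs <- c(msgs, sprintf("classScores must be %d x %d", n, n + 1L))
  }
  if (!is.null(object@featureMap) && length(dim(object@featureMap)) != 3L)
    msgs <- c(msgs, "featureMap must be a 3-d array (C_F x H_F x W_F)")
  if (length(object@label) != 1L)
    msgs <- c(msgs, "label must be a single code or NA")
  if (!is.na(object@label) && !(object@label %in% scanLocations()))
    msgs <- c(msgs, sprintf("unknown scan-location label '%s'", object@label))
  if (length(msgs)) msgs else TRUE
})

#' BinaryMask: pixel set of one segmented class
#'
#' Sparse representation of a per-class binary mask: the 0-based (x, y)
#' coordinates of member pixels (x = column, y = row, origin top-left) plus the
#' raster extent.
#'
#' @slot coords integer n x 2 matrix, columns x then y.
#' @slot width raster width W.
#' @slot height raster height H.
#' @exportClass BinaryMask
setClass("BinaryMask",
  slots = c(coords = "matrix", width = "integer", height = "integer")
)

setValidity("BinaryMask", function(object) {
  msgs <- character()
  cc <- object@coords
  if (ncol(cc) != 2L) msgs <- c(msgs, "coords must have two columns (x, y)")
  if (nrow(cc)) {
    if (min(cc[, 1L]) < 0L || max(cc[, 1L]) >= object@width)
      msgs <- c(msgs, "x coordinates out of [0, W)")
    if (min(cc[, 2L]) < 0L || max(cc[, 2L]) >= object@height)
      msgs <- c(msgs, "y coordinates out of [0, H)")
  }
  if (length(msgs)) msgs else TRUE
})

#' GeometricFeatures: the per-class (N-1) x 10 shape-descriptor matrix
#'
#' One row per non-background class: detection tag T, centroid (L_x, L_y),
#' area fraction S, and morphology [lambda1, lambda2, v1x, v1y, v2x, v2y]
#' (eigenvalues and unit eigenvectors of the pixel-coordinate covariance).
#' Rows of undetected classes are all zeros.
#'
#' @slot V numeric (N-1) x 10 matrix with descriptive column names.
#' @exportClass GeometricFeatures
setClass("GeometricFeatures", slots = c(V = "matrix"))

setValidity("GeometricFeatures", function(object) {
  V <- object@V
  msgs <- character()
  if (ncol(V) != 10L) msgs <- c(msgs, "V must have 10 columns")
  if (nrow(V)) {
    if (!all(V[, 1L] %in% c(0, 1))) msgs <- c(msgs, "tag column must be 0/1")
    if (any(V[, 4L] < 0 | V[, 4L] > 1))
      msgs <- c(msgs, "size fraction must lie in [0, 1]")
    if (any(V[, 5L] < V[, 6L] - 1e-12) || any(V[, 6L] < -1e-12))
      msgs <- c(msgs, "eigenvalues must satisfy lambda1 >= lambda2 >= 0")
    for (j in c(7L, 9L)) {
      nrm <- sqrt(V[, j]^2 + V[, j + 1L]^2)
      if (!all(abs(nrm - 1) < 1e-9 | nrm < 1e-12))
        msgs <- c(msgs, "eigenvector rows must have norm 1 or be all-zero")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' FeatureVector: ordered concatenation of classifier input segments
#'
#' A flat numeric vector assembled from named segments (GAP image features,
#' flattened query embeddings, class scores, geometric features) with the
#' layout recorded so downstream code can recover segment offsets.
#'
#' @slot values numeric vector.
#' @slot layout named integer vector of segment lengths, in concatenation
#'   order.
#' @exportClass FeatureVector
setClass("FeatureVector", slots = c(values = "numeric", layout = "integer"))

setValidity("FeatureVector", function(object) {
  if (length(object@values) != sum(object@layout))
    "total length must equal the sum of declared segment lengths" else TRUE
})

#' ThreeChannelImage: vessel-group classifier input
#'
#' H x W x 3 raster: channel 1 = original intensities inside the segmented
#' vessel area (zero elsewhere), channel 2 = ReLU background mask prediction,
#' channel 3 = ReLU vessel mask prediction.
#'
#' @slot data numeric H x W x 3 array.
#' @exportClass ThreeChannelImage
setClass("ThreeChannelImage", slots = c(data = "array"))

setValidity("ThreeChannelImage", function(object) {
  d <- dim(object@data)
  msgs <- character()
  if (length(d) != 3L || d[3L] != 3L)
    msgs <- c(msgs, "data must be an H x W x 3 array")
  else if (any(object@data[, , 2:3] < 0))
    msgs <- c(msgs, "mask-prediction channels must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' ReferenceSet: grid-sampled clear-data prototypes for KNN voting
#'
#' Clear-data embeddings selected one per occupied cell of a uniform grid laid
#' over their 2-d t-SNE projection, retained with labels for k-nearest-
#' neighbour classification in the full embedding space.
#'
#' @slot embeddings numeric m x d matrix (d = 64 by default), one row per
#'   reference point.
#' @slot labels character vector of scan-location codes, length m.
#' @slot tsne numeric m x 2 matrix of t-SNE coordinates.
#' @slot cells integer m x 2 matrix of (row, col) grid-cell indices, 1-based.
#' @slot gridDim integer length-2 vector (rows, cols).
#' @slot bounds numeric length-4 vector (xmin, xmax, ymin, ymax) of the t-SNE
#'   bounding box the grid was laid over.
#' @slot seed integer seed used for t-SNE and within-cell sampling.
#' @exportClass ReferenceSet
setClass("ReferenceSet",
  slots = c(embeddings = "matrix", labels = "character", tsne = "matrix",
            cells = "matrix", gridDim = "integer", bounds = "numeric",
            seed = "integer")
)

setValidity("ReferenceSet", function(object) {
  m <- nrow(object@embeddings)
  msgs <- character()
  if (length(object@labels) != m || nrow(object@tsne) != m ||
      nrow(object@cells) != m)
    msgs <- c(msgs, "embeddings, labels, tsne and cells must agree in length")
  if (m > prod(object@gridDim))
    msgs <- c(msgs, "more references than grid cells")
  if (m && anyDuplicated(paste(object@cells[, 1L], object@cells[, 2L])))
    msgs <- c(msgs, "at most one reference per grid cell")
  if (length(msgs)) msgs else TRUE
})

#' HierarchyModel: the trained two-level scan-location classifier
#'
#' Bundles the first-level 8-region classifier, the right-subcostal group
#' machinery (sub-step-1 classifier, triplet encoder, reference set) and the
#' longitudinal-group image classifier, together with the configuration used
#' to train them.
#'
#' @slot level1 list; trained 8-class MLP over organ-derived features.
#' @slot group1Substep1 list; trained MLP over liver+vessel features for
#'   ST/RSPV/RSHV.
#' @slot group1Encoder list; trained triplet-loss embedding network.
#' @slot group1Refs ReferenceSet used for KNN voting.
#' @slot group2 list; trained image classifier for SL/EBL.
#' @slot config list of training hyperparameters and seeds.
#' @exportClass HierarchyModel
setClass("HierarchyModel",
  slots = c(level1 = "list", group1Substep1 = "list", group1Encoder = "list",
            group1Refs = "ReferenceSet", group2 = "list", config = "list")
)

#' EvaluationReport: per-class precision/recall/F1 plus confusion matrix
#'
#' @slot perClass data.frame with columns class, support, precision, recall,
#'   f1, zeroDenominator.
#' @slot macro named numeric vector (precision, recall, f1), unweighted means
#'   over classes with non-zero support.
#' @slot confusion integer matrix, rows = true class, cols = predicted class.
#' @slot mode character tag (e.g. hierarchical, non_hierarchical, substep1,
#'   substep2).
#' @slot fold integer fold id (NA if not fold-based).
#' @slot seed integer seed (NA if not applicable).
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  slots = c(perClass = "data.frame", macro = "numeric", confusion = "matrix",
            mode = "character", fold = "integer", seed = "integer")
)
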
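#' ReLU activation of mask predictions
#'
#' Elementwise max(x, 0). ReLU is used instead of a sigmoid so that
#' low-confidence positive mask scores are retained while negative scores are
#' filtered out.
#'
#' @param maskLogits numeric array or matrix of pre-activation mask
#'   predictions.
#' @return Same shape, non-negative.
#' @examples
#' reluMaskPredictions(c(-0.3, 0.7))  # 0.0 0.7
#' @export
reluMaskPredictions <- function(maskLogits) pmax(maskLogits, 0)

#' Build the three-channel image for the SL/EBL classifier
#'
#' Channel 1 carries the original intensities inside the segmented vessel area
#' (zero elsewhere), channel 2 the ReLU background mask prediction and channel
#' 3 the ReLU vessel mask prediction. The vessel segmentation model must have
#' exactly two classes (background, vessel).
#'
#' @param image numeric H x W intensity matrix.
#' @param classMap integer H x W matrix, 0 = background, 1 = vessel.
#' @param reluLogits numeric 2 x H x W array of non-negative mask predictions
#'   (see [reluMaskPredictions()]).
#' @return A [ThreeChannelImage-class].
#' @export
buildThreeChannelImage <- function(image, classMap, reluLogits) {
  d <- dim(reluLogits)
  if (is.null(d) || length(d) != 3L || d[1L] != 2L)
    stop("vessel model must have N = 2 classes (background, vessel)")
  if (!identical(dim(image), dim(classMap)) || !identical(d[2:3], dim(image)))
    stop("image, classMap and reluLogits disagree in spatial dimensions")
  if (any(reluLogits < 0))
    stop("reluLogits must be non-negative; apply reluMaskPredictions() first")
  out <- array(0, c(dim(image), 3L))
  out[, , 1L] <- image * (classMap == 1L)
  out[, , 2L] <- reluLogits[1L, , ]
  out[, , 3L] <- reluLogits[2L, , ]
  new("ThreeChannelImage", data = out)
}

#' @describeIn buildThreeChannelImage the raw H x W x 3 array
#' @param x a \code{ThreeChannelImage}
#' @export
threeChannelData <- function(x) x@data

setMethod("show", "ThreeChannelImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("ThreeChannelImage %dx%d (vessel px: %d)\n", d[1L], d[2L],
              sum(object@data[, , 1L] != 0)))
})

#' Resize and scale a three-channel image for the classifier
#'
#' Bilinear resize to side x side followed by per-channel min-max scaling to
#' [0, 1]; a constant channel maps to all zeros.
#'
#' @param img a [ThreeChannelImage-class].
#' @param side target side length in pixels (>= 8; 224 reproduces the
#'   full-scale protocol, smaller sides are used for desk-scale models).
#' @return Numeric side x side x 3 array with values in [0, 1].
#' @export
preprocessForClassifier <- function(img, side = 224L) {
  stopifnot(is(img, "ThreeChannelImage"), side >= 8L)
  x <- img@data
  out <- array(0, c(side, side, 3L))
  for (ch in 1:3) {
    m <- x[, , ch]
    if (!identical(dim(m), c(side, side)))
      m <- EBImage::resize(m, w = side, h = side, filter = "bilinear")
    rng <- range(m)
    out[, , ch] <- if (rng[2L] > rng[1L]) (m - rng[1L]) / (rng[2L] - rng[1L])
                   else 0
  }
  out
}

#' Export a ThreeChannelImage for visual inspection or pipeline use
#'
#' PNG export clips each channel to 8 bits after scaling to [0, 1] and is
#' lossy, intended only for display; HDF5 export is lossless.
#'
#' @param img a [ThreeChannelImage-class].
#' @param path output path.
#' @param format \code{"png"} or \code{"h5"}.
#' @return The path, invisibly.
#' @export
exportThreeChannelImage <- function(img, path, format = c("png", "h5")) {
  format <- match.arg(format)
  if (format == "png") {
    x <- img@data
    for (ch in 1:3) {
      rng <- range(x[, , ch])
      x[, , ch] <- if (rng[2L] > rng[1L])
        (x[, , ch] - rng[1L]) / (rng[2L] - rng[1L]) else 0
    }
    png::writePNG(x, path)
  } else {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(img@data, path, "three_channel")
  }
  invisible(path)
}
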
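#' Write a SegmentationArtifact to an HDF5 bundle
#'
#' One self-describing HDF5 file per image. Datasets: \code{image},
#' \code{class_map} and, when present, \code{mask_logits},
#' \code{query_embeddings}, \code{feature_map}, \code{class_scores}. Root
#' attributes: \code{subject_id}, \code{label}, \code{n_classes}. Absent
#' optional tensors are simply not stored and are restored as absent on read.
#' Writing the same artifact twice yields byte-identical files.
#'
#' @param artifact a validated [SegmentationArtifact-class].
#' @param path output file path (overwritten if it exists).
#' @return The path, invisibly.
#' @seealso [readArtifact()]
#' @export
writeArtifact <- function(artifact, path) {
  validObject(artifact)
  if (file.exists(path) && unlink(path) != 0L)
    stop("cannot overwrite ", path)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  rhdf5::h5createFile(path)
  rhdf5::h5write(artifact@image, path, "image")
  rhdf5::h5write(artifact@classMap, path, "class_map")
  for (nm in c("maskLogits", "queryEmbeddings", "featureMap", "classScores")) {
    v <- slot(artifact, nm)
    if (!is.null(v)) rhdf5::h5write(v, path, .h5name(nm))
  }
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(artifact@subjectId, fid, "subject_id")
  if (!is.na(artifact@label))            # unlabeled artifacts omit the attr
    rhdf5::h5writeAttribute(artifact@label, fid, "label")
  rhdf5::h5writeAttribute(artifact@nClasses, fid, "n_classes")
  invisible(path)
}

.h5name <- function(slot) {
  c(maskLogits = "mask_logits", queryEmbeddings = "query_embeddings",
    featureMap = "feature_map", classScores = "class_scores")[[slot]]
}

#' Read a SegmentationArtifact from an HDF5 bundle
#'
#' Inverse of [writeArtifact()]: restores all stored tensors, flags missing
#' optional tensors as absent, and validates invariants (a class map whose
#' shape disagrees with the image raises a validation error naming both
#' shapes).
#'
#' @param path path to a bundle written by [writeArtifact()].
#' @return A validated [SegmentationArtifact-class].
#' @export
readArtifact <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  present <- rhdf5::h5ls(path)$name
  need <- c("image", "class_map")
  if (!all(need %in% present))
    stop("bundle lacks required datasets: ",
         paste(setdiff(need, present), collapse = ", "))
  grab <- function(nm) if (nm %in% present) rhdf5::h5read(path, nm) else NULL
  att <- rhdf5::h5readAttributes(path, "/")
  img <- rhdf5::h5read(path, "image")
  cm <- rhdf5::h5read(path, "class_map")
  storage.mode(cm) <- "integer"
  ml <- grab("mask_logits"); fm <- grab("feature_map")
  SegmentationArtifact(
    image = img, classMap = cm,
    maskLogits = if (!is.null(ml)) array(ml, dim(ml)),
    queryEmbeddings = grab("query_embeddings"),
    featureMap = if (!is.null(fm)) array(fm, dim(fm)),
    classScores = grab("class_scores"),
    nClasses = as.integer(att$n_classes),
    subjectId = as.character(att$subject_id),
    label = if (is.null(att$label)) NA_character_ else as.character(att$label))
}

#' Read / write a dataset manifest
#'
#' A manifest is a CSV with columns \code{path}, \code{subject_id},
#' \code{label} mapping artifact bundles to subjects and scan-location codes.
#'
#' @param manifest data.frame with those three columns.
#' @param path CSV file path.
#' @return \code{readManifest}: the manifest data.frame.
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(all(c("path", "subject_id", "label") %in% names(manifest)))
  utils::write.csv(manifest[, c("path", "subject_id", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("path", "subject_id", "label") %in% names(m)))
  m
}

#' Export an image or class map as 8-bit grayscale PNG
#'
#' Images are scaled from [0, 255]; class maps are stored with the raw class
#' index in the 8-bit channel (lossless for N <= 256).
#'
#' @param x numeric intensity matrix or integer class map.
#' @param path output PNG path.
#' @param what \code{"image"} or \code{"class_map"}.
#' @return The path, invisibly.
#' @export
exportPNG <- function(x, path, what = c("image", "class_map")) {
  what <- match.arg(what)
  scaled <- if (what == "image") pmin(pmax(x / 255, 0), 1) else x / 255
  png::writePNG(scaled, path)
  invisible(path)
}

#' Import an 8-bit grayscale PNG written by [exportPNG()]
#'
#' @param path PNG path.
#' @param what \code{"image"} (returns intensities 0-255) or
#'   \code{"class_map"} (returns an integer label matrix).
#' @return Numeric or integer matrix.
#' @export
importPNG <- function(path, what = c("image", "class_map")) {
  what <- match.arg(what)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  out <- round(m * 255)
  if (what == "class_map") storage.mode(out) <- "integer"
  out
}
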
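#' Training configuration for the hierarchical classifier
#'
#' Defaults follow the reference protocol where stated (AdamW, learning rate
#' 1e-4, early stopping with patience 10, two fully connected layers with
#' cross-entropy) and desk-scale choices elsewhere (hidden width 256, batch
#' 64, epoch cap, 32 px vessel-image side, small-CNN learning rate).
#'
#' @param hidden MLP hidden width.
#' @param lr AdamW learning rate for the MLP heads.
#' @param epochs epoch cap for the MLP heads.
#' @param batch mini-batch size.
#' @param patience early-stopping patience (epochs).
#' @param seed master seed; stage seeds are derived from it.
#' @param side vessel-image side length fed to the group-2 classifier.
#' @param group2Lr,group2Epochs training settings of the small CNN.
#' @param knnK neighbours for reference-point voting (default 3).
#' @param gridRows,gridCols reference-selection grid (default 10 x 10).
#' @param group1Routing \code{"knn"} routes every group-1 sample through the
#'   reference-point KNN (sub-step 1 only partitions the training data);
#'   \code{"substep1"} keeps the sub-step-1 MLP decision.
#' @param liverOnlyGeometry restrict the organ geometric segment of the
#'   group-1 feature vector to the liver class.
#' @param triplet a [tripletEncoderConfig()] for the embedding encoder.
#' @return Named list of settings.
#' @export
hierarchyConfig <- function(hidden = 256L, lr = 1e-4, epochs = 500L,
                            batch = 64L, patience = 10L, seed = 1L,
                            side = 32L, group2Lr = 1e-3, group2Epochs = 60L,
                            knnK = 3L, gridRows = 10L, gridCols = 10L,
                            group1Routing = c("knn", "substep1"),
                            liverOnlyGeometry = TRUE,
                            triplet = tripletEncoderConfig()) {
  list(hidden = as.integer(hidden), lr = lr, epochs = as.integer(epochs),
       batch = as.integer(batch), patience = as.integer(patience),
       seed = as.integer(seed), side = as.integer(side), group2Lr = group2Lr,
       group2Epochs = as.integer(group2Epochs), knnK = as.integer(knnK),
       gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
       group1Routing = match.arg(group1Routing),
       liverOnlyGeometry = liverOnlyGeometry, triplet = triplet)
}

.sampleLabels <- function(samples) vapply(samples, `[[`, character(1L), "label")
.sampleSubjects <- function(samples)
  vapply(samples, `[[`, character(1L), "subjectId")

# organ-only feature vector (first hierarchy level)
.organFeatures <- function(sample)
  featureValues(assembleFeatureVector(sample$organ))

# liver + vessel features (group 1): organ feature vector with the geometric
# segment restricted to the liver class, concatenated with the vessel model's
# full feature vector
.group1Features <- function(sample, liverOnly = TRUE)
  c(featureValues(assembleFeatureVector(
      sample$organ, geomClasses = if (liverOnly) 1L else NULL)),
    featureValues(assembleFeatureVector(sample$vessel)))

# concatenated organ + vessel features (non-hierarchical ablation)
.jointFeatures <- function(sample)
  c(featureValues(assembleFeatureVector(sample$organ)),
    featureValues(assembleFeatureVector(sample$vessel)))

.featureMatrix <- function(samples, fn, ...) {
  do.call(rbind, lapply(samples, fn, ...))
}

#' Train the first-level 8-region classifier
#'
#' Two-fully-connected-layer MLP with cross-entropy over the organ-model
#' feature vector (GAP features, query embeddings, class scores, geometric
#' features); organ information alone suffices at this level. Labels are
#' first collapsed to the 8 region groups.
#'
#' @param samples list of samples (see [generateScanSample()]).
#' @param config a [hierarchyConfig()].
#' @return A classifier object for [predictScanLocations()].
#' @export
trainLevel1 <- function(samples, config = hierarchyConfig()) {
  y <- groupLabel(.sampleLabels(samples))
  missing <- setdiff(regionGroups(), y)
  if (length(missing))
    stop("dataset lacks samples for region group(s): ",
         paste(missing, collapse = ", "))
  X <- .featureMatrix(samples, .organFeatures)
  .mlpTrain(X, y, regionGroups(), hidden = config$hidden, lr = config$lr,
            epochs = config$epochs, batch = config$batch,
            patience = config$patience, seed = config$seed)
}

#' Train the group-1 (ST/RSPV/RSHV) two-step classifier
#'
#' Sub-step 1 trains an MLP on liver+vessel feature vectors. Training samples
#' it predicts correctly are taken as clear data; on those, a triplet-loss
#' encoder is trained and a grid-sampled [ReferenceSet-class] built for KNN
#' voting (sub-step 2).
#'
#' @param samples list of samples restricted (or restrictable) to ST, RSPV,
#'   RSHV labels.
#' @param config a [hierarchyConfig()].
#' @return List with \code{substep1} (MLP), \code{encoder}, \code{refs},
#'   \code{clearFraction}.
#' @export
trainGroup1 <- function(samples, config = hierarchyConfig()) {
  g1 <- groupMembers("GROUP_ST_RSPV_RSHV")
  samples <- samples[.sampleLabels(samples) %in% g1]
  y <- .sampleLabels(samples)
  missing <- setdiff(g1, y)
  if (length(missing))
    stop("group-1 training data lacks label(s): ",
         paste(missing, collapse = ", "))
  X <- .featureMatrix(samples, .group1Features,
                      liverOnly = config$liverOnlyGeometry)
  substep1 <- .mlpTrain(X, y, g1, hidden = config$hidden, lr = config$lr,
                        epochs = config$epochs, batch = config$batch,
                        patience = config$patience, seed = config$seed)
  clear <- .mlpPredict(substep1, X) == y
  nClear <- table(factor(y[clear], levels = g1))
  if (any(nClear < 2L))
    stop("degenerate reference set: fewer than 2 clear samples for ",
         paste(g1[nClear < 2L], collapse = ", "))
  tcfg <- config$triplet
  tcfg$seed <- config$seed + 1L
  encoder <- trainTripletEncoder(X[clear, , drop = FALSE], y[clear], tcfg)
  emb <- encodeFeatures(encoder, X[clear, , drop = FALSE])
  refs <- selectReferencePoints(emb, y[clear], config$gridRows,
                                config$gridCols, seed = config$seed + 2L)
  list(substep1 = substep1, encoder = encoder, refs = refs,
       clearFraction = mean(clear),
       liverOnly = config$liverOnlyGeometry)
}

#' Train the group-2 (SL/EBL) image classifier
#'
#' Builds the three-channel vessel image of every sample (vessel-masked
#' intensities plus ReLU background/vessel mask predictions), resizes and
#' scales it, and trains the configured image backbone (desk-scale default: a
#' small CNN; any callable backbone can be substituted downstream).
#'
#' @param samples list of samples restricted (or restrictable) to SL, EBL.
#' @param config a [hierarchyConfig()].
#' @return An image classifier object.
#' @export
trainGroup2 <- function(samples, config = hierarchyConfig()) {
  g2 <- groupMembers("GROUP_SL_EBL")
  samples <- samples[.sampleLabels(samples) %in% g2]
  y <- .sampleLabels(samples)
  missing <- setdiff(g2, y)
  if (length(missing))
    stop("group-2 training data lacks label(s): ",
         paste(missing, collapse = ", "))
  X <- .group2Images(samples, config$side)
  .cnnTrain(X, y, g2, side = config$side, lr = config$group2Lr,
            epochs = config$group2Epochs, patience = config$patience,
            seed = config$seed)
}

.group2Images <- function(samples, side) {
  imgs <- lapply(samples, function(s) {
    v <- s$vessel
    tci <- buildThreeChannelImage(scanImage(v), classMap(v),
                                  reluMaskPredictions(maskLogits(v)))
    preprocessForClassifier(tci, side)
  })
  X <- array(0, c(length(imgs), side, side, 3L))
  for (i in seq_along(imgs)) X[i, , , ] <- imgs[[i]]
  X
}

#' Train the full two-level hierarchical classifier
#'
#' @param samples list of training samples covering all 11 scan locations.
#' @param config a [hierarchyConfig()].
#' @return A [HierarchyModel-class].
#' @export
trainHierarchy <- function(samples, config = hierarchyConfig()) {
  level1 <- trainLevel1(samples, config)
  g1 <- trainGroup1(samples, config)
  group2 <- trainGroup2(samples, config)
  new("HierarchyModel", level1 = level1, group1Substep1 = g1$substep1,
      group1Encoder = g1$encoder, group1Refs = g1$refs, group2 = group2,
      config = c(config, list(clearFraction = g1$clearFraction)))
}

setMethod("show", "HierarchyModel", function(object) {
  cat("HierarchyModel\n")
  cat(sprintf("  level 1: 8-region MLP (val loss %.4f)\n",
              object@level1$valLoss))
  cat(sprintf("  group 1: sub-step-1 MLP + triplet encoder + %d references\n",
              nrow(object@group1Refs@embeddings)))
  cat(sprintf("  group 2: %s image classifier (side %d)\n",
              object@group2$kind, object@group2$side))
  cat(sprintf("  group-1 routing: %s; clear fraction %.2f\n",
              object@config$group1Routing, object@config$clearFraction))
})

#' Predict scan locations with a trained hierarchy
#'
#' Routes each sample through the first level; samples assigned to the
#' ST/RSPV/RSHV group are embedded and classified by reference-point KNN
#' (or by the sub-step-1 MLP, per the model's routing config), samples
#' assigned to the SL/EBL group go through the three-channel image
#' classifier, and all other first-level decisions are final.
#'
#' @param model a [HierarchyModel-class].
#' @param samples list of samples (organ + vessel artifact pairs).
#' @param trace return a data.frame with the level-1 decision and branch
#'   taken instead of a bare label vector.
#' @return Character vector of predicted scan-location codes, or a trace
#'   data.frame with columns predicted, level1, branch.
#' @export
predictScanLocations <- function(model, samples, trace = FALSE) {
  cfg <- model@config
  X1 <- .featureMatrix(samples, .organFeatures)
  l1 <- .mlpPredict(model@level1, X1)
  pred <- l1
  branch <- rep("level1", length(samples))
  isG1 <- l1 == "GROUP_ST_RSPV_RSHV"
  if (any(isG1)) {
    missingVessel <- vapply(samples[isG1], function(s) is.null(s$vessel),
                            logical(1L))
    if (any(missingVessel))
      stop("group-1 routing requires a vessel artifact")
    Xg <- .featureMatrix(samples[isG1], .group1Features,
                         liverOnly = cfg$liverOnlyGeometry)
    if (cfg$group1Routing == "knn") {
      emb <- encodeFeatures(model@group1Encoder, Xg)
      pred[isG1] <- knnClassify(emb, model@group1Refs, k = cfg$knnK)
      branch[isG1] <- "group1_knn"
    } else {
      pred[isG1] <- .mlpPredict(model@group1Substep1, Xg)
      branch[isG1] <- "group1_substep1"
    }
  }
  isG2 <- l1 == "GROUP_SL_EBL"
  if (any(isG2)) {
    missingVessel <- vapply(samples[isG2], function(s) is.null(s$vessel),
                            logical(1L))
    if (any(missingVessel))
      stop("group-2 routing requires a vessel artifact")
    Xi <- .group2Images(samples[isG2], model@group2$side)
    pred[isG2] <- .cnnPredict(model@group2, Xi)
    branch[isG2] <- "group2_cnn"
  }
  if (trace) data.frame(predicted = pred, level1 = l1, branch = branch)
  else pred
}

#' Train the non-hierarchical 11-class ablation classifier
#'
#' A single two-fully-connected-layer MLP over the concatenation of the
#' organ-model and vessel-model feature vectors, classifying all 11 scan
#' locations at once. Same optimizer and stopping rule as the hierarchy's
#' MLP heads.
#'
#' @param samples list of samples covering all 11 scan locations.
#' @param config a [hierarchyConfig()].
#' @return A classifier object for [predictNonHierarchical()].
#' @export
trainNonHierarchical <- function(samples, config = hierarchyConfig()) {
  y <- .sampleLabels(samples)
  missing <- setdiff(scanLocations(), y)
  if (length(missing))
    stop("dataset lacks samples for label(s): ",
         paste(missing, collapse = ", "))
  X <- .featureMatrix(samples, .jointFeatures)
  .mlpTrain(X, y, scanLocations(), hidden = config$hidden, lr = config$lr,
            epochs = config$epochs, batch = config$batch,
            patience = config$patience, seed = config$seed)
}

#' @rdname trainNonHierarchical
#' @param model classifier returned by \code{trainNonHierarchical}.
#' @param samples list of samples.
#' @export
predictNonHierarchical <- function(model, samples) {
  .mlpPredict(model, .featureMatrix(samples, .jointFeatures))
}
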
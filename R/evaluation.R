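#' Subject-wise cross-validation folds
#'
#' Enumerates every way of choosing \code{trainK} training subjects from the
#' given subjects; the remainder of each combination forms the test side.
#' With 5 subjects and 3 training subjects this yields the C(5,3) = 10 folds
#' of the reference protocol. Order is deterministic (combination order).
#'
#' @param subjects character vector of distinct subject identifiers.
#' @param trainK number of training subjects per fold (default 3).
#' @return List of folds, each a list with \code{train} and \code{test}.
#' @examples
#' length(subjectFolds(paste0("s", 1:5)))  # 10
#' @export
subjectFolds <- function(subjects, trainK = 3L) {
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects)) stop("subjects must be distinct")
  if (trainK >= length(subjects))
    stop("trainK must be smaller than the number of subjects")
  combos <- utils::combn(subjects, trainK, simplify = FALSE)
  lapply(combos, function(tr) list(train = tr, test = setdiff(subjects, tr)))
}

#' Score predictions with per-class precision, recall and F1
#'
#' Computes the confusion matrix and, per class, precision = TP/(TP+FP),
#' recall = TP/(TP+FN) and their harmonic-mean F1. Classes with zero support
#' in the truth are reported absent from the per-class table (they still
#' occupy confusion-matrix columns when predicted). Zero-denominator metrics
#' are defined as 0 and flagged. Macro averages are unweighted means over the
#' classes with support.
#'
#' @param truth,predicted character vectors of equal length; labels must be
#'   scan-location or region-group codes (or supply \code{classes}).
#' @param classes optional class universe (character, canonical order).
#' @param mode,fold,seed metadata tags stored in the report.
#' @return An [EvaluationReport-class].
#' @export
scorePredictions <- function(truth, predicted, classes = NULL, mode = "",
                             fold = NA_integer_, seed = NA_integer_) {
  stopifnot(length(truth) == length(predicted), length(truth) > 0L)
  if (is.null(classes)) {
    universe <- c(scanLocations(), regionGroups())
    bad <- setdiff(c(truth, predicted), universe)
    if (length(bad))
      stop("unknown label(s): ", paste(unique(bad), collapse = ", "))
    classes <- intersect(universe, c(truth, predicted))
  } else {
    bad <- setdiff(c(truth, predicted), classes)
    if (length(bad))
      stop("label(s) outside the declared class set: ",
           paste(unique(bad), collapse = ", "))
  }
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  conf <- table(truth = tf, predicted = pf)
  conf <- matrix(as.integer(conf), nrow = length(classes),
                 dimnames = dimnames(conf))
  support <- rowSums(conf)
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- support - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  flag <- (tp + fp == 0) | (tp + fn == 0) | (prec + rec == 0)
  keep <- support > 0
  perClass <- data.frame(class = classes, support = support,
                         precision = prec, recall = rec, f1 = f1,
                         zeroDenominator = flag,
                         row.names = NULL)[keep, , drop = FALSE]
  macro <- c(precision = mean(perClass$precision),
             recall = mean(perClass$recall), f1 = mean(perClass$f1))
  new("EvaluationReport", perClass = perClass, macro = macro,
      confusion = conf, mode = mode, fold = as.integer(fold),
      seed = as.integer(seed))
}

#' @describeIn scorePredictions per-class metric table
#' @param x an \code{EvaluationReport}
#' @export
reportPerClass <- function(x) x@perClass

#' @describeIn scorePredictions macro-averaged precision/recall/F1
#' @export
reportMacro <- function(x) x@macro

#' @describeIn scorePredictions confusion matrix (rows = truth)
#' @export
reportConfusion <- function(x) x@confusion

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport [%s] fold=%s seed=%s\n", object@mode,
              object@fold, object@seed))
  cat(sprintf("  macro: precision %.3f  recall %.3f  F1 %.3f\n",
              object@macro["precision"], object@macro["recall"],
              object@macro["f1"]))
  print(object@perClass, digits = 3)
})

#' Write an EvaluationReport as CSV and JSON
#'
#' CSV holds the per-class rows; JSON additionally carries the macro
#' averages, confusion matrix and a hash of the configuration used.
#'
#' @param report an [EvaluationReport-class].
#' @param stem output path stem (\code{<stem>.csv}, \code{<stem>.json}).
#' @param config optional configuration list to hash into the JSON.
#' @return The stem, invisibly.
#' @export
writeReport <- function(report, stem, config = NULL) {
  utils::write.csv(report@perClass, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(
    mode = report@mode, fold = report@fold, seed = report@seed,
    macro = as.list(report@macro),
    perClass = report@perClass,
    confusion = report@confusion,
    configHash = if (!is.null(config)) digest::digest(config) else NULL
  ), paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

# train on one fold's training subjects, predict the test subjects, score
.runMode <- function(samples, mode, fold, config, seed, foldId = NA_integer_) {
  cfg <- config
  cfg$seed <- as.integer(seed)
  subj <- .sampleSubjects(samples)
  trainS <- samples[subj %in% fold$train]
  testS <- samples[subj %in% fold$test]
  truth <- .sampleLabels(testS)
  g1 <- groupMembers("GROUP_ST_RSPV_RSHV")
  if (mode == "hierarchical") {
    model <- trainHierarchy(trainS, cfg)
    pred <- predictScanLocations(model, testS)
    scorePredictions(truth, pred, classes = scanLocations(), mode = mode,
                     fold = foldId, seed = seed)
  } else if (mode == "non_hierarchical") {
    model <- trainNonHierarchical(trainS, cfg)
    pred <- predictNonHierarchical(model, testS)
    scorePredictions(truth, pred, classes = scanLocations(), mode = mode,
                     fold = foldId, seed = seed)
  } else if (mode %in% c("substep1", "substep2")) {
    trainS <- trainS[.sampleLabels(trainS) %in% g1]
    testS <- testS[.sampleLabels(testS) %in% g1]
    truth <- .sampleLabels(testS)
    fit <- trainGroup1(trainS, cfg)
    X <- .featureMatrix(testS, .group1Features, liverOnly = fit$liverOnly)
    pred <- if (mode == "substep1") .mlpPredict(fit$substep1, X) else
      knnClassify(encodeFeatures(fit$encoder, X), fit$refs, k = cfg$knnK)
    scorePredictions(truth, pred, classes = g1, mode = mode,
                     fold = foldId, seed = seed)
  } else stop("unknown mode: ", mode)
}

#' Compare classification modes over folds and seeds
#'
#' Runs each requested mode (hierarchical, non_hierarchical, substep1,
#' substep2) over the given subject folds and seeds, collecting macro-F1 per
#' run. A failed training run is recorded as NA and the comparison proceeds.
#'
#' @param samples list of samples (all subjects).
#' @param modes character vector of at least 2 mode tags (duplicates allowed).
#' @param seeds integer vector of seeds.
#' @param folds list from [subjectFolds()]; default all folds of the
#'   subjects present.
#' @param config a [hierarchyConfig()].
#' @param trainK training subjects per fold when \code{folds} is NULL.
#' @return List with \code{table} (per-mode mean/sd macro-F1), \code{cells}
#'   (per run), and \code{verdicts} (pairwise directional comparisons of
#'   mean macro-F1).
#' @export
compareModes <- function(samples, modes, seeds = 1L, folds = NULL,
                         config = hierarchyConfig(), trainK = 3L) {
  if (length(modes) < 2L) stop("need at least 2 modes to compare")
  if (is.null(folds))
    folds <- subjectFolds(unique(.sampleSubjects(samples)), trainK)
  cells <- expand.grid(mode = modes, foldId = seq_along(folds), seed = seeds,
                       stringsAsFactors = FALSE)
  cells$macroF1 <- NA_real_
  for (i in seq_len(nrow(cells))) {
    rep <- tryCatch(
      .runMode(samples, cells$mode[i], folds[[cells$foldId[i]]], config,
               cells$seed[i], cells$foldId[i]),
      error = function(e) NULL)
    if (!is.null(rep)) cells$macroF1[i] <- reportMacro(rep)["f1"]
  }
  tab <- do.call(rbind, lapply(unique(modes), function(m) {
    v <- cells$macroF1[cells$mode == m]
    data.frame(mode = m, meanMacroF1 = mean(v, na.rm = TRUE),
               sdMacroF1 = stats::sd(v), n = sum(!is.na(v)))
  }))
  verdicts <- NULL
  um <- unique(modes)
  if (length(um) >= 2L) {
    pairs <- utils::combn(um, 2L, simplify = FALSE)
    verdicts <- do.call(rbind, lapply(pairs, function(p) {
      a <- tab$meanMacroF1[tab$mode == p[1L]]
      b <- tab$meanMacroF1[tab$mode == p[2L]]
      data.frame(a = p[1L], b = p[2L],
                 verdict = if (a >= b) paste(p[1L], ">=", p[2L]) else
                   paste(p[1L], "<", p[2L]))
    }))
  }
  list(table = tab, cells = cells, verdicts = verdicts)
}

#' Macro-F1 of a label-permutation chance baseline
#'
#' Scores predictions drawn by permuting the truth labels; any informative
#' classifier should exceed this.
#'
#' @param truth character vector of labels.
#' @param seed permutation seed.
#' @param classes optional class universe.
#' @return Macro F1 of the permuted predictions.
#' @export
chanceMacroF1 <- function(truth, seed = 1L, classes = NULL) {
  set.seed(seed)
  perm <- sample(truth)
  unname(reportMacro(scorePredictions(truth, perm, classes = classes,
                                      mode = "chance"))["f1"])
}
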
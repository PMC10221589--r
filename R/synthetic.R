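# Synthetic segmentation-artifact generator. Emulates, for each of the 11
# scan locations, the class-dependent organ presence/position/size, vessel
# morphology (Bezier strokes with branches), blurred signed-distance mask
# logits, and low-dimensional class-conditional embedding structure with
# per-subject offsets, so that every pipeline stage is trainable and testable
# without clinical data.

.hashSeed <- function(...) {
  abs(digest::digest2int(paste(..., sep = "|"))) %% 2147483646L + 1L
}

#' Default per-location geometry and embedding specification
#'
#' Encodes the study conditions the generator emulates: which organs appear
#' at each scan location and where, how large and how elongated they are, the
#' vessel stroke geometry (length, width, orientation, curvature, branch
#' count), and the embedding noise scales. ST/RSPV/RSHV share one organ
#' distribution and differ only in vessel morphology and embeddings; SL and
#' EBL share organ distributions and have deliberately close vessel
#' embeddings (their separation lives in the rendered vessel shape), so the
#' hierarchy's second level is genuinely needed.
#'
#' @param overlap ambiguity level in [0, 1] applied to the two confusable
#'   groups: it shrinks within-group embedding and geometry separation and
#'   makes each grouped frame, with this probability, drift toward another
#'   group member (drift weight uniform in (0.25, 0.75)). The recorded label
#'   always stays the session's location, so strongly drifted frames carry
#'   labels their features contradict, as when the probe slips during a
#'   scan. 0 = fully separable.
#' @param H,W raster size in pixels.
#' @param cF encoder feature-map channels; @param cQ embedding dimension.
#' @param seed base seed from which all class/subject mean vectors derive.
#' @return Nested list with \code{$global} and \code{$locations}.
#' @export
defaultScanSpecs <- function(overlap = 0, H = 128L, W = 128L, cF = 32L,
                             cQ = 32L, seed = 101L) {
  stopifnot(overlap >= 0, overlap <= 1)
  org <- function(p, cx, cy, area, ar, theta)
    list(p = p, cx = cx, cy = cy, area = area, ar = ar, theta = theta)
  none <- org(0, 0.5, 0.5, 0.05, 1.5, 0)
  ves <- function(p, cx, cy, len, width, angle, curv, branches, detect = 1)
    list(p = p, cx = cx, cy = cy, len = len, width = width, angle = angle,
         curv = curv, branches = branches, detect = detect)
  genericVessel <- ves(0.4, 0.50, 0.50, 0.35, 0.025, 0.3, 0.15, 1L)
  loc <- function(liver, kidney = none, gallbladder = none,
                  vessel = genericVessel, ov = 0)
    list(organs = list(liver = liver, kidney = kidney,
                       gallbladder = gallbladder),
         vessel = vessel, ambiguityOverlap = ov)
  slLiver <- org(1, 0.45, 0.45, 0.18, 1.6, 0.3)
  g1Liver <- org(1, 0.50, 0.42, 0.30, 1.9, 0.1)
  # ambiguity is concentrated in the right-subcostal group; the longitudinal
  # pair discriminates comparatively well, so it receives half the level
  ovG2 <- overlap / 2
  locations <- list(
    SL   = loc(slLiver, vessel = ves(1, 0.50, 0.50, 0.62, 0.045, pi / 2,
                                     0.04, 1L, detect = 0.55), ov = ovG2),
    ST   = loc(g1Liver, vessel = ves(1, 0.50, 0.45, 0.55, 0.030, 0.0,
                                     0.10, 2L), ov = overlap),
    RSPV = loc(g1Liver, vessel = ves(1, 0.42, 0.58, 0.50, 0.040, 0.5,
                                     0.18, 3L), ov = overlap),
    RSLT = loc(org(1, 0.55, 0.50, 0.40, 2.3, 0.0)),
    LD   = loc(org(1, 0.50, 0.25, 0.24, 2.0, 0.0)),
    RSHV = loc(g1Liver, vessel = ves(1, 0.62, 0.60, 0.52, 0.028, -0.9,
                                     0.05, 2L), ov = overlap),
    GBL  = loc(org(0.9, 0.35, 0.35, 0.15, 1.6, 0.4),
               gallbladder = org(1, 0.62, 0.62, 0.05, 2.8, 0.9)),
    EBL  = loc(slLiver, vessel = ves(1, 0.56, 0.60, 0.30, 0.020, 1.2,
                                     0.30, 1L, detect = 0.55), ov = ovG2),
    RIA  = loc(org(1, 0.33, 0.52, 0.28, 1.7, 0.6)),
    RIP  = loc(org(1, 0.67, 0.55, 0.28, 1.7, -0.6)),
    LK   = loc(org(1, 0.40, 0.40, 0.22, 1.7, 0.2),
               kidney = org(1, 0.66, 0.66, 0.08, 2.0, 0.7))
  )
  list(global = list(H = as.integer(H), W = as.integer(W),
                     cF = as.integer(cF), cQ = as.integer(cQ),
                     seed = as.integer(seed),
                     centroidSd = 0.02, areaRelSd = 0.10,
                     embSdOrgan = 0.5, embSdVessel = 1.2,
                     subjSdGeom = 0.012, subjSdEmb = 0.3,
                     scoreNoise = 0.3),
       locations = locations)
}

#' Validate a scan-location specification set
#'
#' @param specs nested list as produced by [defaultScanSpecs()].
#' @return TRUE invisibly; otherwise an error describing the violation.
#' @export
validateScanSpecs <- function(specs) {
  stopifnot(is.list(specs$global), is.list(specs$locations))
  miss <- setdiff(scanLocations(), names(specs$locations))
  if (length(miss)) stop("missing locations: ", paste(miss, collapse = ", "))
  for (nm in names(specs$locations)) {
    l <- specs$locations[[nm]]
    probs <- c(vapply(l$organs, `[[`, numeric(1L), "p"), l$vessel$p)
    if (any(probs < 0 | probs > 1))
      stop(nm, ": presence probabilities must lie in [0, 1]")
    areas <- vapply(l$organs, `[[`, numeric(1L), "area")
    if (any(areas <= 0 | areas >= 1))
      stop(nm, ": area fractions must lie in (0, 1)")
    if (l$ambiguityOverlap < 0 || l$ambiguityOverlap > 1)
      stop(nm, ": ambiguity_overlap must lie in [0, 1]")
  }
  if (specs$locations$LK$organs$kidney$p != 1)
    stop("LK must have kidney presence 1.0")
  if (specs$locations$GBL$organs$gallbladder$p != 1)
    stop("GBL must have gallbladder presence 1.0")
  invisible(TRUE)
}

#' Read / write a specification set as YAML
#'
#' @param specs a specification set; @param path YAML file path.
#' @return \code{readScanSpecs}: the validated specification list.
#' @export
writeScanSpecs <- function(specs, path) {
  validateScanSpecs(specs)
  yaml::write_yaml(specs, path, precision = 12L)
  invisible(path)
}

#' @rdname writeScanSpecs
#' @export
readScanSpecs <- function(path) {
  specs <- yaml::read_yaml(path)
  specs$global[c("H", "W", "cF", "cQ", "seed")] <-
    lapply(specs$global[c("H", "W", "cF", "cQ", "seed")], as.integer)
  validateScanSpecs(specs)
  specs
}

# --- deterministic mean vectors -------------------------------------------

.meanVec <- function(dim, ...) {
  withr::with_seed(.hashSeed(...), stats::rnorm(dim))
}

.subjectOffsets <- function(subjectId, specs) {
  g <- specs$global
  withr::with_seed(.hashSeed("subject", subjectId, g$seed), list(
    geom = stats::rnorm(2L, 0, g$subjSdGeom),
    embOrgan = stats::rnorm(g$cQ, 0, g$subjSdEmb),
    embVessel = stats::rnorm(g$cQ, 0, g$subjSdEmb),
    fmOrgan = stats::rnorm(g$cF, 0, g$subjSdEmb),
    fmVessel = stats::rnorm(g$cF, 0, g$subjSdEmb)))
}

# Vessel-side embedding mean for a label, including the group-pooling and
# overlap-shrink structure described in defaultScanSpecs().
.vesselEmbMean <- function(label, specs) {
  g <- specs$global
  grp <- groupLabel(label)
  ov <- specs$locations[[label]]$ambiguityOverlap
  if (grp == "GROUP_ST_RSPV_RSHV") {
    mus <- lapply(groupMembers(grp), function(l)
      .meanVec(g$cQ, "vemb", l, g$seed))
    names(mus) <- groupMembers(grp)
    muG <- Reduce(`+`, mus) / length(mus)
    (1 - 0.6 * ov) * mus[[label]] + 0.6 * ov * muG
  } else if (grp == "GROUP_SL_EBL") {
    muG <- .meanVec(g$cQ, "vemb_group", grp, g$seed)
    muL <- .meanVec(g$cQ, "vemb", label, g$seed)
    muG + (1 - 0.6 * ov) * 0.35 * muL
  } else {
    # vessels are not a location cue outside the two confusable groups:
    # all singleton regions share one nonspecific vessel embedding mean
    .meanVec(g$cQ, "vemb_nonspecific", g$seed)
  }
}

.vesselFmMean <- function(label, specs) {
  g <- specs$global
  grp <- groupLabel(label)
  ov <- specs$locations[[label]]$ambiguityOverlap
  if (grp %in% c("GROUP_ST_RSPV_RSHV", "GROUP_SL_EBL")) {
    mus <- lapply(groupMembers(grp), function(l)
      .meanVec(g$cF, "vfm", l, g$seed))
    names(mus) <- groupMembers(grp)
    muG <- Reduce(`+`, mus) / length(mus)
    (1 - 0.6 * ov) * mus[[label]] + 0.6 * ov * muG
  } else .meanVec(g$cF, "vfm_nonspecific", g$seed)
}

# --- rasterization --------------------------------------------------------

.ellipseMask <- function(H, W, cx, cy, a, b, theta) {
  x <- matrix(rep(0:(W - 1L), each = H), H, W)
  y <- matrix(rep(0:(H - 1L), W), H, W)
  u <- cos(theta) * (x - cx) + sin(theta) * (y - cy)
  v <- -sin(theta) * (x - cx) + cos(theta) * (y - cy)
  (u / a)^2 + (v / b)^2 <= 1
}

# distance-to-stroke mask for a quadratic Bezier with constant width
.bezierMask <- function(H, W, p0, p1, p2, width) {
  ts <- seq(0, 1, length.out = 60L)
  px <- (1 - ts)^2 * p0[1L] + 2 * (1 - ts) * ts * p1[1L] + ts^2 * p2[1L]
  py <- (1 - ts)^2 * p0[2L] + 2 * (1 - ts) * ts * p1[2L] + ts^2 * p2[2L]
  x <- matrix(rep(0:(W - 1L), each = H), H, W)
  y <- matrix(rep(0:(H - 1L), W), H, W)
  D <- matrix(Inf, H, W)
  for (i in seq_along(ts)) D <- pmin(D, (x - px[i])^2 + (y - py[i])^2)
  D <= (width / 2)^2
}

# blurred signed distance map of a binary mask; strongly negative when the
# class is absent so ReLU/sigmoid behaviour sees realistic values
.signedDistance <- function(mask01) {
  if (!any(mask01)) return(matrix(-5, nrow(mask01), ncol(mask01)))
  if (all(mask01)) return(matrix(5, nrow(mask01), ncol(mask01)))
  inside <- EBImage::distmap(mask01)
  outside <- EBImage::distmap(1 - mask01)
  inside - outside
}

.maskLogitsFrom <- function(classMap, nClasses) {
  H <- nrow(classMap); W <- ncol(classMap)
  out <- array(0, c(nClasses, H, W))
  for (cl in seq_len(nClasses) - 1L) {
    sd <- .signedDistance(classMap == cl)
    out[cl + 1L, , ] <- EBImage::gblur(sd, sigma = 1.5) / 3
  }
  out
}

.classScoresFrom <- function(classMap, nClasses, noise) {
  S <- matrix(stats::rnorm(nClasses * (nClasses + 1L), -2, noise),
              nClasses, nClasses + 1L)
  for (cl in seq_len(nClasses) - 1L) {
    if (cl == 0L || any(classMap == cl))
      S[cl + 1L, cl + 1L] <- 3 + stats::rnorm(1L, 0, noise)
    else
      S[cl + 1L, nClasses + 1L] <- 3 + stats::rnorm(1L, 0, noise)
  }
  S
}

.featureMapFrom <- function(mu, cF, noiseSd = 0.3) {
  array(mu, c(cF, 8L, 8L)) +
    array(stats::rnorm(cF * 64L, 0, noiseSd), c(cF, 8L, 8L))
}

.clip255 <- function(x) pmin(pmax(x, 0), 255)

# --- sample generation ----------------------------------------------------

.renderOrganArtifact <- function(label, specs, subjectId, subjOff) {
  g <- specs$global
  H <- g$H; W <- g$W
  cm <- matrix(0L, H, W)
  organs <- specs$locations[[label]]$organs
  for (i in seq_along(organs)) {
    sp <- organs[[i]]
    if (stats::runif(1L) >= sp$p) next
    cx <- (sp$cx + subjOff$geom[1L] + stats::rnorm(1L, 0, g$centroidSd)) * W
    cy <- (sp$cy + subjOff$geom[2L] + stats::rnorm(1L, 0, g$centroidSd)) * H
    area <- max(0.004, sp$area * (1 + stats::rnorm(1L, 0, g$areaRelSd)))
    areaPx <- area * H * W
    a <- sqrt(areaPx * sp$ar / pi)
    b <- areaPx / (pi * a)
    theta <- sp$theta + stats::rnorm(1L, 0, 0.08)
    cm[.ellipseMask(H, W, cx, cy, a, b, theta)] <- i
  }
  img <- .clip255(30 + 12 * matrix(stats::rnorm(H * W), H, W) +
                    55 * (cm == 1L) + 40 * (cm == 2L) + 75 * (cm == 3L))
  grp <- groupLabel(label)
  nC <- 4L
  emb <- matrix(stats::rnorm(g$cQ * nC, 0, g$embSdOrgan), g$cQ, nC)
  for (cl in seq_len(nC) - 1L) {
    if (cl > 0L && !any(cm == cl)) next
    emb[, cl + 1L] <- emb[, cl + 1L] +
      .meanVec(g$cQ, "oemb", grp, cl, g$seed) + subjOff$embOrgan
  }
  fm <- .featureMapFrom(.meanVec(g$cF, "ofm", grp, g$seed) + subjOff$fmOrgan,
                        g$cF)
  SegmentationArtifact(
    image = img, classMap = cm,
    maskLogits = .maskLogitsFrom(cm, nC),
    queryEmbeddings = emb, featureMap = fm,
    classScores = .classScoresFrom(cm, nC, g$scoreNoise),
    nClasses = nC, subjectId = subjectId, label = label)
}

# numeric-field blend of two vessel geometry specs (branch count kept
# from the first)
.blendVesselSpec <- function(a, b, w) {
  out <- a
  for (f in c("cx", "cy", "len", "width", "angle", "curv"))
    out[[f]] <- (1 - w) * a[[f]] + w * b[[f]]
  out
}

.renderVesselArtifact <- function(label, specs, subjectId, subjOff) {
  g <- specs$global
  H <- g$H; W <- g$W
  locSpec <- specs$locations[[label]]
  vs <- locSpec$vessel
  ov <- locSpec$ambiguityOverlap
  grp <- groupLabel(label)
  grouped <- grp %in% c("GROUP_ST_RSPV_RSHV", "GROUP_SL_EBL")
  # overlap shrinks the whole group's geometric separation ...
  if (grouped && ov > 0) {
    others <- lapply(groupMembers(grp), function(l)
      specs$locations[[l]]$vessel)
    avg <- others[[1L]]
    for (f in c("cx", "cy", "len", "width", "angle", "curv"))
      avg[[f]] <- mean(vapply(others, `[[`, numeric(1L), f))
    vs <- .blendVesselSpec(vs, avg, 0.6 * ov)
  }
  # ... and makes individual frames drift toward another member: the session
  # label is retained even when the drift passes the midpoint, because the
  # recorded location is the examiner's intent, not the frame content
  ambT <- 0
  otherLabel <- NULL
  if (grouped && stats::runif(1L) < ov) {
    otherLabel <- sample(setdiff(groupMembers(grp), label), 1L)
    ambT <- stats::runif(1L, 0.25, 0.75)
    vs <- .blendVesselSpec(vs, specs$locations[[otherLabel]]$vessel, ambT)
  }
  cm <- matrix(0L, H, W)
  present <- stats::runif(1L) < vs$p
  # the vessel may exist yet go undetected by the segmentation (common for
  # the longitudinal views): the hard mask and query embedding degrade while
  # the soft mask predictions still carry the structure
  detected <- present && stats::runif(1L) < vs$detect
  strokeMask <- NULL
  if (present) {
    # incidental vessels at singleton locations are erratic: their pose keeps
    # changing from frame to frame and carries no location information
    geomSd <- if (grouped) g$centroidSd else 0.08
    angSd <- if (grouped) 0.06 else 0.8
    cx <- (vs$cx + subjOff$geom[1L] + stats::rnorm(1L, 0, geomSd)) * W
    cy <- (vs$cy + subjOff$geom[2L] + stats::rnorm(1L, 0, geomSd)) * H
    ang <- vs$angle + stats::rnorm(1L, 0, angSd)
    half <- vs$len * W / 2
    d <- c(cos(ang), sin(ang))
    nrmv <- c(-sin(ang), cos(ang))
    ctr <- c(cx, cy)
    p0 <- ctr - d * half
    p2 <- ctr + d * half
    p1 <- ctr + nrmv * vs$curv * vs$len * W
    wpx <- max(1.5, vs$width * W * (1 + stats::rnorm(1L, 0, 0.15)))
    m <- .bezierMask(H, W, p0, p1, p2, wpx)
    if (vs$branches > 1L) for (b in seq_len(vs$branches - 1L)) {
      t0 <- 0.3 + 0.4 * (b - 1L) / max(1L, vs$branches - 2L + 1L)
      bx <- (1 - t0)^2 * p0 + 2 * (1 - t0) * t0 * p1 + t0^2 * p2
      bang <- ang + (if (b %% 2L) 0.7 else -0.7) + stats::rnorm(1L, 0, 0.05)
      bd <- c(cos(bang), sin(bang))
      bend <- bx + bd * half * 0.7
      bmid <- (bx + bend) / 2 + c(-bd[2L], bd[1L]) * vs$curv * half * 0.4
      m <- m | .bezierMask(H, W, bx, bmid, bend, wpx * 0.8)
    }
    strokeMask <- m
    if (detected) cm[m] <- 1L
  }
  img <- .clip255(90 + 12 * matrix(stats::rnorm(H * W), H, W) -
                    65 * (if (present) strokeMask else cm == 1L))
  mu <- .vesselEmbMean(label, specs)
  if (ambT > 0)
    mu <- (1 - ambT) * mu + ambT * .vesselEmbMean(otherLabel, specs)
  noiseSd <- g$embSdVessel * (if (ambT > 0) 1.5 else 1)
  emb <- matrix(stats::rnorm(g$cQ * 2L, 0, noiseSd), g$cQ, 2L)
  if (present) {
    embScale <- if (detected) 1 else 0.35
    emb[, 2L] <- emb[, 2L] + embScale * (mu + subjOff$embVessel)
  }
  fmMu <- .vesselFmMean(label, specs)
  if (ambT > 0)
    fmMu <- (1 - ambT) * fmMu + ambT * .vesselFmMean(otherLabel, specs)
  fm <- .featureMapFrom(fmMu + subjOff$fmVessel, g$cF)
  logitMap <- cm
  if (present && !detected) logitMap <- matrix(as.integer(strokeMask), H, W)
  logits <- .maskLogitsFrom(logitMap, 2L)
  if (present && !detected) logits <- 0.6 * logits
  SegmentationArtifact(
    image = img, classMap = cm,
    maskLogits = logits,
    queryEmbeddings = emb, featureMap = fm,
    classScores = .classScoresFrom(cm, 2L, g$scoreNoise),
    nClasses = 2L, subjectId = subjectId, label = label)
}

#' Generate one synthetic organ/vessel artifact pair
#'
#' Renders the organ-segmentation and vessel-segmentation artifacts of one
#' simulated ultrasound frame at the given scan location: elliptical organ
#' blobs and curvilinear vessel strokes per the specification, Gaussian-
#' blurred signed-distance mask logits, label-conditional Gaussian query
#' embeddings and feature maps, and class scores consistent with the classes
#' present. The subject identifier perturbs geometry and embeddings through a
#' fixed per-subject offset, emulating inter-subject variability.
#' Deterministic for fixed (label, specs, subject, seed).
#'
#' @param label scan-location code.
#' @param specs specification set from [defaultScanSpecs()].
#' @param subjectId subject identifier string.
#' @param seed integer seed for this sample.
#' @return List with elements \code{organ} and \code{vessel} (both
#'   [SegmentationArtifact-class]), \code{label} and \code{subjectId}.
#' @export
generateScanSample <- function(label, specs = defaultScanSpecs(),
                               subjectId = "s1", seed = 1L) {
  stopifnot(label %in% scanLocations())
  validateScanSpecs(specs)
  subjOff <- .subjectOffsets(subjectId, specs)
  set.seed(seed)
  organ <- .renderOrganArtifact(label, specs, subjectId, subjOff)
  vessel <- .renderVesselArtifact(label, specs, subjectId, subjOff)
  list(organ = organ, vessel = vessel, label = label, subjectId = subjectId)
}

#' Generate a balanced multi-subject synthetic dataset
#'
#' \code{nPerClass} samples for each of the 11 scan locations, assigned
#' round-robin to the subjects (per-class subject counts differ by at most
#' one). With \code{dir} set, artifact pairs are written as HDF5 bundles
#' (\code{<stem>_organ.h5}, \code{<stem>_vessel.h5}) and the manifest CSV as
#' \code{manifest.csv}; otherwise the dataset is kept in memory.
#' Deterministic for a fixed seed.
#'
#' @param nPerClass samples per scan location (>= 1).
#' @param subjects character vector of at least 2 subject identifiers.
#' @param specs specification set.
#' @param seed integer base seed.
#' @param dir optional output directory.
#' @return List with \code{samples} (list of [generateScanSample()] results)
#'   and \code{manifest} (data.frame path/subject_id/label).
#' @export
generateDataset <- function(nPerClass, subjects, specs = defaultScanSpecs(),
                            seed = 1L, dir = NULL) {
  stopifnot(nPerClass >= 1L)
  if (length(subjects) < 2L) stop("need at least 2 subjects")
  validateScanSpecs(specs)
  labels <- scanLocations()
  samples <- list()
  rows <- list()
  k <- 0L
  for (li in seq_along(labels)) {
    for (i in seq_len(nPerClass)) {
      k <- k + 1L
      subj <- subjects[((i - 1L) %% length(subjects)) + 1L]
      sampleSeed <- (seed %% 1000000L) * 2000L + li * 150L + i
      s <- generateScanSample(labels[li], specs, subj, sampleSeed)
      stem <- sprintf("%s_%03d", labels[li], i)
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        writeArtifact(s$organ, file.path(dir, paste0(stem, "_organ.h5")))
        writeArtifact(s$vessel, file.path(dir, paste0(stem, "_vessel.h5")))
      }
      samples[[k]] <- s
      rows[[k]] <- data.frame(path = stem, subject_id = subj,
                              label = labels[li])
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) writeManifest(manifest, file.path(dir, "manifest.csv"))
  list(samples = samples, manifest = manifest)
}

#' Load a dataset written by [generateDataset()] back into memory
#'
#' @param dir directory containing \code{manifest.csv} and the HDF5 bundles.
#' @return Same structure as [generateDataset()].
#' @export
loadDataset <- function(dir) {
  manifest <- readManifest(file.path(dir, "manifest.csv"))
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    stem <- file.path(dir, manifest$path[i])
    list(organ = readArtifact(paste0(stem, "_organ.h5")),
         vessel = readArtifact(paste0(stem, "_vessel.h5")),
         label = manifest$label[i], subjectId = manifest$subject_id[i])
  })
  list(samples = samples, manifest = manifest)
}

# Interpolate two artifacts: masks through a signed-distance-field blend,
# dense tensors through a convex blend.
.blendArtifact <- function(x, y, t) {
  stopifnot(x@nClasses == y@nClasses, identical(dim(x@image), dim(y@image)))
  n <- x@nClasses
  H <- nrow(x@image); W <- ncol(x@image)
  best <- matrix(-Inf, H, W)
  cm <- matrix(0L, H, W)
  for (cl in seq_len(n - 1L)) {
    sdB <- (1 - t) * .signedDistance(x@classMap == cl) +
      t * .signedDistance(y@classMap == cl)
    upd <- sdB > 0 & sdB > best
    best[upd] <- sdB[upd]
    cm[upd] <- cl
  }
  bl <- function(a, b) if (is.null(a) || is.null(b)) NULL else
    (1 - t) * a + t * b
  src <- if (t < 0.5) x else y
  SegmentationArtifact(
    image = bl(x@image, y@image), classMap = cm,
    maskLogits = bl(x@maskLogits, y@maskLogits),
    queryEmbeddings = bl(x@queryEmbeddings, y@queryEmbeddings),
    featureMap = bl(x@featureMap, y@featureMap),
    classScores = bl(x@classScores, y@classScores),
    nClasses = n, subjectId = src@subjectId, label = src@label)
}

#' Interpolate two samples into an ambiguous sample
#'
#' Emulates the effect of slight probe motion between two scan locations:
#' masks are interpolated through their signed-distance fields, embeddings
#' and other dense tensors through a convex blend at mixing weight \code{t}.
#' The label is taken from the nearer endpoint (\code{t < 0.5} keeps
#' \code{a}'s label).
#'
#' @param a,b samples from [generateScanSample()] with equal image dimensions.
#' @param t mixing weight in [0, 1]; 0 returns \code{a}'s content, 1
#'   \code{b}'s.
#' @return A blended sample (same structure).
#' @export
makeAmbiguousPair <- function(a, b, t) {
  if (t < 0 || t > 1) stop("t must lie in [0, 1]")
  organ <- .blendArtifact(a$organ, b$organ, t)
  vessel <- .blendArtifact(a$vessel, b$vessel, t)
  src <- if (t < 0.5) a else b
  list(organ = organ, vessel = vessel, label = src$label,
       subjectId = src$subjectId)
}
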
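test_that("scan-location vocabulary and grouping are consistent", {
  expect_length(scanLocations(), 11L)
  expect_length(unique(scanLocations()), 11L)
  expect_length(regionGroups(), 8L)
  g <- groupLabel(scanLocations())
  expect_setequal(unique(g), regionGroups())          # surjective onto 8
  expect_identical(groupLabel("ST"), "GROUP_ST_RSPV_RSHV")
  expect_identical(groupLabel("EBL"), "GROUP_SL_EBL")
  expect_identical(groupLabel("LK"), "LK")
  # fibers: the two merged groups plus six singletons
  fib <- split(scanLocations(), g)
  expect_setequal(fib$GROUP_ST_RSPV_RSHV, c("ST", "RSPV", "RSHV"))
  expect_setequal(fib$GROUP_SL_EBL, c("SL", "EBL"))
  expect_true(all(lengths(fib[setdiff(names(fib),
    c("GROUP_ST_RSPV_RSHV", "GROUP_SL_EBL"))]) == 1L))
  expect_error(groupLabel("XX"), "unknown")
})

test_that("artifact construction validates shapes and labels", {
  img <- matrix(0, 4, 4)
  cm <- matrix(0L, 4, 4)
  a <- SegmentationArtifact(image = img, classMap = cm, nClasses = 3L,
                            maskLogits = array(0, c(3, 4, 4)))
  expect_s4_class(a, "SegmentationArtifact")
  expect_error(
    SegmentationArtifact(image = matrix(0, 2, 2), classMap = cm,
                         nClasses = 3L),
    "2x2")
  expect_error(
    SegmentationArtifact(image = img, classMap = matrix(3L, 4, 4),
                         nClasses = 3L),
    "classMap values")
  expect_error(
    SegmentationArtifact(image = img, classMap = cm, nClasses = 3L,
                         label = "BOGUS"),
    "unknown scan-location")
  expect_error(
    SegmentationArtifact(image = img, classMap = cm, nClasses = 3L,
                         queryEmbeddings = matrix(0, 8, 2)),
    "columns")
})

test_that("HDF5 bundles round-trip artifacts exactly and deterministically", {
  withr::with_seed(7, {
    s <- generateScanSample("GBL", testSpecs(), "tA", 31L)
  })
  p1 <- withr::local_tempfile(fileext = ".h5")
  p2 <- withr::local_tempfile(fileext = ".h5")
  writeArtifact(s$organ, p1)
  back <- readArtifact(p1)
  expect_equal(back@image, s$organ@image)
  expect_identical(back@classMap, s$organ@classMap)
  expect_equal(back@maskLogits, s$organ@maskLogits)
  expect_equal(back@queryEmbeddings, s$organ@queryEmbeddings)
  expect_equal(back@classScores, s$organ@classScores)
  expect_identical(scanLabel(back), "GBL")
  expect_identical(subjectId(back), "tA")
  writeArtifact(s$organ, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_error(readArtifact(file.path(tempdir(), "nope.h5")), "no such file")
})

test_that("absent optional tensors survive the round trip as absent", {
  a <- SegmentationArtifact(image = matrix(1, 5, 6),
                            classMap = matrix(0L, 5, 6), nClasses = 2L,
                            maskLogits = array(0, c(2, 5, 6)))
  p <- withr::local_tempfile(fileext = ".h5")
  writeArtifact(a, p)
  back <- readArtifact(p)
  expect_null(featureMap(back))
  expect_null(queryEmbeddings(back))
  expect_null(classScores(back))
  expect_equal(maskLogits(back), a@maskLogits)
})

test_that("class map from logits matches a brute-force argmax with the low-index tie rule", {
  # hand case: tie between channels 2 and 3 resolves to the lower index
  lg <- array(c(0.2, 0.9, 0.9), c(3, 1, 1))
  expect_identical(classMapFromLogits(lg), matrix(1L, 1, 1))
  lg0 <- array(0, c(2, 3, 3)); lg0[1, , ] <- 1
  expect_identical(classMapFromLogits(lg0), matrix(0L, 3, 3))
  withr::with_seed(42, {
    for (rep in 1:20) {
      logits <- array(sample(seq(-1, 1, by = 0.25), 3 * 4 * 4, TRUE),
                      c(3, 4, 4))   # coarse values force frequent ties
      expect_identical(classMapFromLogits(logits), oracleArgmaxMap(logits))
    }
  })
  expect_error(classMapFromLogits(array(0, c(1, 2, 2))), "at least 2")
  expect_error(classMapFromLogits(array(numeric(0), c(0, 0, 0))), "non-empty")
})

test_that("binary masks partition the non-background pixels", {
  cm <- matrix(0L, 3, 3)
  expect_true(all(vapply(binaryMasks(cm, 4L),
                         function(m) nrow(maskCoords(m)) == 0L, TRUE)))
  cm[2, 3] <- 2L
  ms <- binaryMasks(cm, 4L)
  expect_identical(maskCoords(ms[[2]]), cbind(x = 2L, y = 1L))
  expect_identical(nrow(maskCoords(ms[[1]])), 0L)
  withr::with_seed(11, {
    for (rep in 1:15) {
      cm <- matrix(sample(0:3, 48, TRUE), 6, 8)
      ms <- binaryMasks(cm, 4L)
      keys <- lapply(ms, function(m)
        paste(maskCoords(m)[, 1L], maskCoords(m)[, 2L]))
      expect_identical(sum(lengths(keys)), sum(cm != 0L))   # coverage
      expect_identical(anyDuplicated(unlist(keys)), 0L)     # disjoint
      for (i in 1:3)
        expect_identical(length(keys[[i]]), sum(cm == i))
    }
  })
  expect_error(binaryMasks(matrix(5L, 2, 2), 4L), "label 5")
})

test_that("PNG export round-trips images and class maps", {
  p <- withr::local_tempfile(fileext = ".png")
  img <- matrix(sample(0:255, 30, TRUE), 5, 6)
  exportPNG(img, p, "image")
  expect_equal(importPNG(p, "image"), img, ignore_attr = TRUE)
  cm <- matrix(sample(0:3, 30, TRUE), 5, 6)
  exportPNG(cm, p, "class_map")
  expect_identical(importPNG(p, "class_map"), matrix(as.integer(cm), 5, 6),
                   ignore_attr = TRUE)
})

test_that("manifest CSV round-trips", {
  m <- data.frame(path = c("a", "b"), subject_id = c("s1", "s2"),
                  label = c("SL", "LK"))
  p <- withr::local_tempfile(fileext = ".csv")
  writeManifest(m, p)
  expect_identical(readManifest(p), m)
})
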
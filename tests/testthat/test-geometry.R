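test_that("global average pooling is the per-channel spatial mean", {
  expect_equal(globalAveragePool(array(5, c(3, 2, 2))), rep(5, 3))
  fm <- array(0, c(2, 3, 4))
  fm[1, , ] <- matrix(0:11, 3, 4)     # mean 5.5 by direct sum
  expect_equal(globalAveragePool(fm), c(5.5, 0))
  expect_equal(globalAveragePool(array(0, c(4, 2, 2))), rep(0, 4))
  expect_error(globalAveragePool(array(0, c(2, 0, 3))), "spatial")
})

test_that("tag, centroid and size fraction behave per definition", {
  empty <- BinaryMask(matrix(integer(0), 0, 2), 4L, 4L)
  expect_identical(classTag(empty), 0)
  expect_identical(classTag(BinaryMask(cbind(3L, 5L), 8L, 8L)), 1)
  expect_equal(maskCentroid(BinaryMask(cbind(c(0L, 2L), c(0L, 0L)), 4L, 4L)),
               c(x = 1, y = 0))
  expect_equal(maskCentroid(BinaryMask(cbind(3L, 5L), 8L, 8L)),
               c(x = 3, y = 5))
  full <- binaryMasks(matrix(1L, 4, 4), 2L)[[1]]
  expect_equal(maskCentroid(full), c(x = 1.5, y = 1.5))
  expect_error(maskCentroid(empty), "empty")
  expect_equal(sizeFraction(empty), 0)
  expect_equal(sizeFraction(full), 1)
  eight <- BinaryMask(cbind(rep(0:1, 4), rep(0:3, each = 2)), 4L, 4L)
  expect_equal(sizeFraction(eight), 0.5)
})

test_that("morphology handles degenerate and collinear masks", {
  single <- BinaryMask(cbind(3L, 5L), 8L, 8L)
  expect_equal(maskMorphology(single), c(0, 0, 1, 0, 0, 1))
  hline <- BinaryMask(cbind(0:4, rep(2L, 5)), 8L, 8L)
  m <- maskMorphology(hline)
  expect_equal(m[2], 0)                       # zero minor eigenvalue
  expect_equal(m[3:4], c(1, 0))               # major axis along x
  # solid square: covariance is a scaled identity -> canonical basis
  sq <- BinaryMask(cbind(rep(0:2, 3), rep(0:2, each = 3)), 8L, 8L)
  ms <- maskMorphology(sq)
  expect_equal(ms[1], ms[2])
  expect_equal(ms[3:6], c(1, 0, 0, 1))
  expect_error(maskMorphology(BinaryMask(matrix(integer(0), 0, 2), 4L, 4L)),
               "empty")
})

test_that("centroid, size and morphology match brute-force oracles on 200 random masks", {
  withr::with_seed(99, {
    for (rep in 1:200) {
      m <- randomMask()
      expect_equal(unname(maskCentroid(m)), oracleCentroid(m),
                   tolerance = 1e-9)
      expect_equal(sizeFraction(m),
                   nrow(maskCoords(m)) / (12 * 16), tolerance = 1e-9)
      expect_equal(maskMorphology(m), oracleMorphology(m), tolerance = 1e-9)
    }
  })
})

test_that("morphology eigenvectors are orthonormal for non-degenerate masks", {
  withr::with_seed(5, {
    for (rep in 1:50) {
      m <- randomMask()
      if (nrow(unique(maskCoords(m))) < 2L) next
      v <- maskMorphology(m)
      V <- matrix(v[3:6], 2, 2)
      expect_equal(crossprod(V), diag(2), tolerance = 1e-9)
    }
  })
})

test_that("geometric feature matrix has the declared shape with zero rows for undetected classes", {
  cm <- matrix(0L, 6, 6)
  cm[2:4, 2:4] <- 1L
  V <- geometryMatrix(geometricFeatureMatrix(cm, 4L))
  expect_identical(dim(V), c(3L, 10L))
  expect_true(all(V[2:3, ] == 0))
  expect_identical(unname(V[1, 1]), 1)
  expect_true(all(geometryMatrix(
    geometricFeatureMatrix(matrix(0L, 4, 4), 4L)) == 0))
  # validity holds on random maps, and rows agree with the component ops
  withr::with_seed(13, {
    for (rep in 1:20) {
      cm <- matrix(sample(0:3, 60, TRUE, prob = c(0.7, 0.1, 0.1, 0.1)), 6, 10)
      gf <- geometricFeatureMatrix(cm, 4L)
      expect_s4_class(gf, "GeometricFeatures")
      V <- geometryMatrix(gf)
      ms <- binaryMasks(cm, 4L)
      for (i in 1:3) {
        if (nrow(maskCoords(ms[[i]])) == 0L) {
          expect_true(all(V[i, ] == 0))
        } else {
          expect_equal(unname(V[i, 2:3]), oracleCentroid(ms[[i]]),
                       tolerance = 1e-9)
          expect_equal(unname(V[i, 4]), sizeFraction(ms[[i]]))
          expect_equal(unname(V[i, 5:10]), oracleMorphology(ms[[i]]),
                       tolerance = 1e-9)
        }
      }
    }
  })
})

test_that("geometric features are translation-covariant", {
  base <- matrix(0L, 10, 12)
  base[2:4, 2:5] <- 1L
  shifted <- matrix(0L, 10, 12)
  shifted[5:7, 6:9] <- 1L                     # dy = 3, dx = 4
  V0 <- geometryMatrix(geometricFeatureMatrix(base, 2L))
  V1 <- geometryMatrix(geometricFeatureMatrix(shifted, 2L))
  expect_equal(V1[1, 2:3], V0[1, 2:3] + c(loc_x = 4, loc_y = 3))
  expect_equal(V1[1, c(1, 4:10)], V0[1, c(1, 4:10)])
})

test_that("feature vectors concatenate declared segments in fixed order", {
  s <- withr::with_seed(3, generateScanSample("ST", testSpecs(), "tA", 17L))
  fvAll <- assembleFeatureVector(s$organ)
  lay <- featureLayout(fvAll)
  expect_identical(names(lay),
                   c("gap", "queries", "class_scores", "geometric"))
  expect_identical(unname(lay), c(16L, 16L * 4L, 4L * 5L, 3L * 10L))
  expect_identical(length(featureValues(fvAll)), sum(lay))
  expect_identical(unname(featureOffsets(fvAll)),
                   c(0L, 16L, 16L + 64L, 16L + 64L + 20L))
  # geometric-only with N=4 flattens to 30 values
  fvG <- assembleFeatureVector(s$organ, parts = "geometric")
  expect_identical(length(featureValues(fvG)), 30L)
  # restricting the geometric segment to the liver row
  fvL <- assembleFeatureVector(s$organ, parts = "geometric", geomClasses = 1L)
  expect_identical(length(featureValues(fvL)), 10L)
  expect_identical(featureValues(fvL),
                   featureValues(fvG)[1:10])
  # determinism
  expect_identical(featureValues(assembleFeatureVector(s$organ)),
                   featureValues(fvAll))
  # requesting an absent part names it
  bare <- SegmentationArtifact(image = matrix(0, 4, 4),
                               classMap = matrix(0L, 4, 4), nClasses = 2L)
  expect_error(assembleFeatureVector(bare, parts = "gap"), "gap")
  expect_error(assembleFeatureVector(bare, parts = "queries"), "queries")
})
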
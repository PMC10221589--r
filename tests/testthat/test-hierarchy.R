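# Pipeline-level tests run on a small shared synthetic dataset (64 px
# rasters, reduced network sizes) so the full suite stays quick.

hierData <- local({
  ds <- generateDataset(10L, testSubjects, testSpecs(), seed = 55L)
  lab <- vapply(ds$samples, `[[`, character(1), "label")
  sub <- vapply(ds$samples, `[[`, character(1), "subjectId")
  list(samples = ds$samples, lab = lab, sub = sub,
       train = ds$samples[sub %in% c("t1", "t2", "t3")],
       test = ds$samples[sub == "t4"])
})

test_that("level-1 training demands all region groups and is seed-deterministic", {
  noGBL <- hierData$train[vapply(hierData$train, `[[`, character(1),
                                 "label") != "GBL"]
  expect_error(trainLevel1(noGBL, testConfig()), "GBL")
  m1 <- trainLevel1(hierData$train, testConfig(3L))
  m2 <- trainLevel1(hierData$train, testConfig(3L))
  expect_identical(digest::digest(m1$net$layers), digest::digest(m2$net$layers))
  X <- do.call(rbind, lapply(hierData$test, sonoloc:::.organFeatures))
  pred <- sonoloc:::.mlpPredict(m1, X)
  expect_true(all(pred %in% regionGroups()))
})

test_that("group-1 training partitions clear data and builds full-coverage references", {
  fit <- suppressWarnings(trainGroup1(hierData$train, testConfig(3L)))
  expect_gte(fit$clearFraction, 0.95)         # overlap-free spec
  expect_setequal(unique(refLabels(fit$refs)), c("ST", "RSPV", "RSHV"))
  fit2 <- suppressWarnings(trainGroup1(hierData$train, testConfig(3L)))
  expect_identical(refEmbeddings(fit2$refs), refEmbeddings(fit$refs))
  expect_identical(refLabels(fit2$refs), refLabels(fit$refs))
  onlyST <- hierData$train[vapply(hierData$train, `[[`, character(1),
                                  "label") == "ST"]
  expect_error(trainGroup1(onlyST, testConfig()), "RSPV")
})

test_that("group-2 image classifier learns SL vs EBL and needs both labels", {
  fit <- trainGroup2(hierData$train, testConfig(3L))
  te <- hierData$test[vapply(hierData$test, `[[`, character(1), "label")
                      %in% c("SL", "EBL")]
  X <- sonoloc:::.group2Images(te, fit$side)
  pred <- sonoloc:::.cnnPredict(fit, X)
  truth <- vapply(te, `[[`, character(1), "label")
  expect_gt(mean(pred == truth), 0.7)
  onlySL <- hierData$train[vapply(hierData$train, `[[`, character(1),
                                  "label") == "SL"]
  expect_error(trainGroup2(onlySL, testConfig()), "EBL")
})

test_that("hierarchical routing is sound and composes the stage operations", {
  model <- suppressWarnings(trainHierarchy(hierData$train, testConfig(3L)))
  tr <- predictScanLocations(model, hierData$test, trace = TRUE)
  # routing soundness: predictions stay inside the fiber of the level-1 call
  for (i in seq_len(nrow(tr))) {
    if (tr$level1[i] %in% regionGroups()[3:8]) {
      expect_identical(tr$predicted[i], tr$level1[i])
      expect_identical(tr$branch[i], "level1")
    } else if (tr$level1[i] == "GROUP_ST_RSPV_RSHV") {
      expect_true(tr$predicted[i] %in% c("ST", "RSPV", "RSHV"))
      expect_identical(tr$branch[i], "group1_knn")
    } else {
      expect_true(tr$predicted[i] %in% c("SL", "EBL"))
      expect_identical(tr$branch[i], "group2_cnn")
    }
  }
  # stagewise oracle: composing the stages manually reproduces predict
  X1 <- do.call(rbind, lapply(hierData$test, sonoloc:::.organFeatures))
  l1 <- sonoloc:::.mlpPredict(model@level1, X1)
  expect_identical(tr$level1, l1)
  manual <- l1
  g1 <- l1 == "GROUP_ST_RSPV_RSHV"
  if (any(g1)) {
    Xg <- do.call(rbind, lapply(hierData$test[g1], sonoloc:::.group1Features))
    manual[g1] <- knnClassify(encodeFeatures(model@group1Encoder, Xg),
                              model@group1Refs, k = 3L)
  }
  g2 <- l1 == "GROUP_SL_EBL"
  if (any(g2)) {
    Xi <- sonoloc:::.group2Images(hierData$test[g2], model@group2$side)
    manual[g2] <- sonoloc:::.cnnPredict(model@group2, Xi)
  }
  expect_identical(tr$predicted, manual)
  # a singleton-region sample never touches the second level
  lkIdx <- which(vapply(hierData$test, `[[`, character(1), "label") == "LK")
  expect_true(all(tr$branch[lkIdx][tr$level1[lkIdx] == "LK"] == "level1"))
  # substep1 routing variant stays in the group fiber too
  cfgS <- testConfig(3L); cfgS$group1Routing <- "substep1"
  modelS <- suppressWarnings(trainHierarchy(hierData$train, cfgS))
  trS <- predictScanLocations(modelS, hierData$test, trace = TRUE)
  expect_true(all(trS$predicted[trS$level1 == "GROUP_ST_RSPV_RSHV"] %in%
                    c("ST", "RSPV", "RSHV")))
  # missing vessel artifact raises a routing error naming the branch
  broken <- lapply(hierData$test, function(s) { s$vessel <- NULL; s })
  expect_error(predictScanLocations(model, broken), "vessel artifact")
})

test_that("non-hierarchical ablation trains on joint features and is deterministic", {
  m <- trainNonHierarchical(hierData$samples, testConfig(4L))
  pred <- predictNonHierarchical(m, hierData$test)
  expect_true(all(pred %in% scanLocations()))
  m2 <- trainNonHierarchical(hierData$samples, testConfig(4L))
  expect_identical(predictNonHierarchical(m2, hierData$test), pred)
  noLD <- hierData$samples[hierData$lab != "LD"]
  expect_error(trainNonHierarchical(noLD, testConfig()), "LD")
})
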
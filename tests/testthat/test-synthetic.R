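test_that("specification sets validate and round-trip through YAML", {
  specs <- defaultScanSpecs()
  expect_true(validateScanSpecs(specs))
  p <- withr::local_tempfile(fileext = ".yaml")
  writeScanSpecs(specs, p)
  back <- readScanSpecs(p)
  expect_equal(back$locations, specs$locations)
  expect_equal(back$global, specs$global)
  bad <- specs
  bad$locations$LK$organs$kidney$p <- 0.5
  expect_error(validateScanSpecs(bad), "LK")
  bad2 <- specs
  bad2$locations$SL$ambiguityOverlap <- 1.5
  expect_error(validateScanSpecs(bad2), "ambiguity_overlap")
})

test_that("generated samples are deterministic, valid and label-consistent", {
  specs <- testSpecs()
  s1 <- generateScanSample("LK", specs, "tA", 5L)
  s2 <- generateScanSample("LK", specs, "tA", 5L)
  expect_identical(s1$organ@image, s2$organ@image)
  expect_identical(s1$vessel@queryEmbeddings, s2$vessel@queryEmbeddings)
  expect_true(validObject(s1$organ))
  expect_true(validObject(s1$vessel))
  expect_identical(scanLabel(s1$organ), "LK")
  expect_identical(s1$vessel@nClasses, 2L)
  # a different subject or seed changes the content
  expect_false(identical(
    generateScanSample("LK", specs, "tB", 5L)$organ@image, s1$organ@image))
  # kidney (class 2) present in every LK draw; gallbladder (3) in every GBL
  for (i in 1:10) {
    expect_true(any(classMap(
      generateScanSample("LK", specs, "tA", 100L + i)$organ) == 2L))
    expect_true(any(classMap(
      generateScanSample("GBL", specs, "tA", 200L + i)$organ) == 3L))
  }
})

test_that("label-conditional statistics match the specification", {
  specs <- testSpecs()
  n <- 120L
  areas <- numeric(n)
  liverPresent <- logical(n)
  for (i in seq_len(n)) {
    s <- generateScanSample("GBL", specs, "tA", 3000L + i)
    cm <- classMap(s$organ)
    liverPresent[i] <- any(cm == 1L)
    areas[i] <- mean(cm == 3L)
  }
  pL <- specs$locations$GBL$organs$liver$p
  se <- sqrt(pL * (1 - pL) / n)
  expect_lt(abs(mean(liverPresent) - pL), 3 * se)
  # gallbladder area fraction: mean within 3 standard errors of the spec,
  # allowing a pixelation/overdraw margin on the target itself
  target <- specs$locations$GBL$organs$gallbladder$area
  expect_lt(abs(mean(areas) - target),
            3 * stats::sd(areas) / sqrt(n) + 0.15 * target)
})

test_that("group-1 vessel centroids are well separated without overlap", {
  specs <- testSpecs(overlap = 0)
  g1 <- c("ST", "RSPV", "RSHV")
  cent <- lapply(g1, function(lb) {
    t(vapply(1:40, function(i) {
      v <- generateScanSample(lb, specs, "tA", 500L + i)$vessel
      m <- binaryMasks(classMap(v), 2L)[[1]]
      maskCentroid(m)
    }, numeric(2L)))
  })
  sds <- vapply(cent, function(M) sqrt(mean(apply(M, 2, stats::var))),
                numeric(1))
  for (i in 1:2) for (j in (i + 1):3) {
    d <- sqrt(sum((colMeans(cent[[i]]) - colMeans(cent[[j]]))^2))
    expect_gt(d, 3 * max(sds[c(i, j)]))
  }
})

test_that("datasets are balanced, round-robin assigned and reproducible", {
  specs <- testSpecs()
  ds <- generateDataset(6L, testSubjects, specs, seed = 9L)
  expect_identical(nrow(ds$manifest), 66L)
  expect_true(all(table(ds$manifest$label) == 6L))
  byClass <- table(ds$manifest$label, ds$manifest$subject_id)
  expect_true(all(apply(byClass, 1, function(r) diff(range(r)) <= 1L)))
  ds2 <- generateDataset(6L, testSubjects, specs, seed = 9L)
  expect_identical(digest::digest(ds2$manifest), digest::digest(ds$manifest))
  expect_identical(digest::digest(ds2$samples[[7]]$organ@image),
                   digest::digest(ds$samples[[7]]$organ@image))
  expect_error(generateDataset(5L, "onlyone", specs), "2 subjects")
})

test_that("disk datasets round-trip through manifest and bundles", {
  dir <- withr::local_tempdir()
  specs <- testSpecs()
  ds <- generateDataset(1L, c("tA", "tB"), specs, seed = 4L, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- loadDataset(dir)
  expect_identical(back$manifest$label, ds$manifest$label)
  i <- 3L
  expect_equal(back$samples[[i]]$organ@maskLogits,
               ds$samples[[i]]$organ@maskLogits)
  expect_identical(back$samples[[i]]$subjectId, ds$samples[[i]]$subjectId)
})

test_that("ambiguous interpolation honors endpoints, midpoint and labels", {
  specs <- testSpecs()
  a <- generateScanSample("ST", specs, "tA", 21L)
  b <- generateScanSample("RSPV", specs, "tA", 22L)
  at0 <- makeAmbiguousPair(a, b, 0)
  expect_identical(at0$organ@classMap, a$organ@classMap)
  expect_equal(at0$vessel@queryEmbeddings, a$vessel@queryEmbeddings)
  expect_identical(at0$label, "ST")
  at1 <- makeAmbiguousPair(a, b, 1)
  expect_identical(at1$vessel@classMap, b$vessel@classMap)
  expect_identical(at1$label, "RSPV")
  mid <- makeAmbiguousPair(a, b, 0.5)
  expect_equal(mid$vessel@queryEmbeddings,
               (a$vessel@queryEmbeddings + b$vessel@queryEmbeddings) / 2)
  expect_identical(makeAmbiguousPair(a, b, 0.4)$label, "ST")
  expect_true(validObject(mid$organ))
  expect_error(makeAmbiguousPair(a, b, 1.2), "0, 1")
})

test_that("increasing overlap degrades sub-step-1 accuracy monotonically", {
  acc <- vapply(c(0, 0.4, 0.8), function(ov) {
    specs <- testSpecs(overlap = ov)
    ds <- generateDataset(10L, testSubjects, specs, seed = 6L)
    lab <- vapply(ds$samples, `[[`, character(1), "label")
    sub <- vapply(ds$samples, `[[`, character(1), "subjectId")
    keep <- lab %in% c("ST", "RSPV", "RSHV")
    tr <- keep & sub %in% c("t1", "t2", "t3")
    te <- keep & !sub %in% c("t1", "t2", "t3")
    fit <- suppressWarnings(trainGroup1(ds$samples[tr], testConfig(2L)))
    X <- do.call(rbind, lapply(ds$samples[te], sonoloc:::.group1Features))
    mean(sonoloc:::.mlpPredict(fit$substep1, X) ==
           lab[te])
  }, numeric(1))
  expect_true(all(diff(acc) <= 0.05))   # non-increasing up to sampling noise
  expect_gt(acc[1], acc[3])
})
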
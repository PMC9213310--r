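# Network architecture, gradients, training mechanics, tiling inference,
# and the cross-validation fold structure.

test_that("network configuration and shape contracts hold", {
  cfg <- networkConfig(baseFilters = 8L)
  m <- buildNetwork(cfg, seed = 1)
  x <- array(rnorm(24^3 * 2), c(24, 24, 24, 2))
  out <- boneSCT:::netForward(modelWeights(m), m@netConfig, x)$out
  expect_identical(dim(out), c(24L, 24L, 24L))
  expect_error(networkConfig(patchSize = 25L), "divisible")
  # parameter count is monotone in width
  p8 <- parameterCount(buildNetwork(networkConfig(baseFilters = 8L)))
  p16 <- parameterCount(buildNetwork(networkConfig(baseFilters = 16L)))
  expect_gt(p16, p8)
  # a zero final layer maps any input to exactly zero
  w <- modelWeights(m)
  w$head$w[] <- 0; w$head$b <- 0
  m0 <- m; m0@weights <- w
  out0 <- boneSCT:::netForward(m0@weights, m0@netConfig, x)$out
  expect_true(all(out0 == 0))
})

test_that("backward pass matches finite differences", {
  cfg <- tinyNet()
  m <- buildNetwork(cfg, seed = 5)
  w <- modelWeights(m)
  # randomize biases away from zero so no ReLU sits exactly on its kink
  flat <- boneSCT:::flattenParams(w)
  set.seed(77)
  for (k in grep("\\.b$", names(flat), value = TRUE))
    flat[[k]] <- flat[[k]] + rnorm(length(flat[[k]]), sd = 0.05)
  w <- boneSCT:::assignFlat(w, flat)
  set.seed(6)
  x <- array(rnorm(8^3 * 2, sd = 0.5), c(8, 8, 8, 2))
  y <- array(rnorm(8^3, sd = 0.5), c(8, 8, 8))
  lossFn <- function(wi) {
    out <- boneSCT:::netForward(wi, cfg, x)$out
    mean((out - y)^2)
  }
  fw <- boneSCT:::netForward(w, cfg, x, cache = TRUE)
  g <- boneSCT:::gradAsWeights(
    boneSCT:::netBackward(w, cfg, fw$cache, 2 * (fw$out - y) / length(y)))
  fg <- boneSCT:::flattenParams(g)
  fwt <- boneSCT:::flattenParams(w)
  set.seed(7)
  eps <- 1e-6
  for (k in names(fwt)) {
    for (ii in sample(length(fwt[[k]]), min(3, length(fwt[[k]])))) {
      wp <- fwt; wp[[k]][ii] <- wp[[k]][ii] + eps
      wm <- fwt; wm[[k]][ii] <- wm[[k]][ii] - eps
      num <- (lossFn(boneSCT:::assignFlat(w, wp)) -
                lossFn(boneSCT:::assignFlat(w, wm))) / (2 * eps)
      expect_equal(fg[[k]][ii], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", k, ii))
    }
  }
})

test_that("zero learning rate leaves weights untouched; seeds reproduce", {
  case <- tinyCase("osteoblastic", seed = 61, shape = c(32, 32, 32))
  cfg <- networkConfig(baseFilters = 2L, patchSize = 16L)
  m0 <- buildNetwork(cfg, seed = 3)
  tc0 <- trainConfig(learningRate = 0, epochs = 1L, batchSize = 2L,
                     patchesPerVolume = 4L, augment = FALSE, seed = 2L)
  tm0 <- train(m0, list(case), case, tc0)
  expect_identical(boneSCT:::flattenParams(modelWeights(tm0)),
                   boneSCT:::flattenParams(modelWeights(m0)))

  tc <- trainConfig(learningRate = 1e-3, epochs = 2L, batchSize = 2L,
                    patchesPerVolume = 4L, seed = 2L)
  a <- train(m0, list(case), case, tc)
  b <- train(m0, list(case), case, tc)
  expect_identical(trainingHistory(a), trainingHistory(b))
  expect_identical(boneSCT:::flattenParams(modelWeights(a)),
                   boneSCT:::flattenParams(modelWeights(b)))
  expect_error(train(m0, list(), case, tc), "empty training set")
})

test_that("tiled inference preserves constants and single-patch identity", {
  cfg <- networkConfig(baseFilters = 2L, patchSize = 16L)
  m <- buildNetwork(cfg, seed = 9)
  w <- modelWeights(m)
  w$head$w[] <- 0
  w$head$b <- 0.25   # constant model on the normalized scale
  m@weights <- w
  mr <- array(abs(rnorm(40 * 36 * 32)), c(40, 36, 32))
  sct <- predictVolume(m, mr, mr)
  expectHU <- denormalizeCT(array(0.25, c(1, 1, 1)))[1]
  expect_lt(max(abs(sct - expectHU)), 1e-6)

  # a volume of exactly one patch equals a single forward pass
  m2 <- buildNetwork(cfg, seed = 10)
  mr1 <- array(abs(rnorm(16^3)) + 0.1, c(16, 16, 16))
  mr2 <- array(abs(rnorm(16^3)) + 0.1, c(16, 16, 16))
  sct1 <- predictVolume(m2, mr1, mr2)
  n1 <- normValues(normalizeMR(mr1, 95))
  n2 <- normValues(normalizeMR(mr2, 95))
  direct <- boneSCT:::netForward(modelWeights(m2), m2@netConfig,
                                 array(c(n1, n2), c(16, 16, 16, 2)))$out
  expect_equal(sct1, array(pmin(pmax(denormalizeCT(direct), -1024), 3071),
                           dim(direct)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(predictVolume(m2, mr1[1:8, , ], mr2[1:8, , ]), "smaller")
})

test_that("models serialize and reload with bit-identical predictions", {
  cfg <- tinyNet()
  m <- buildNetwork(cfg, seed = 21)
  x1 <- array(abs(rnorm(12^3)) + 0.1, c(12, 12, 12))
  x2 <- array(abs(rnorm(12^3)) + 0.1, c(12, 12, 12))
  p1 <- predictVolume(m, x1, x2)
  tmp <- tempfile(fileext = ".rds")
  saveModel(m, tmp)
  m2 <- loadModel(tmp)
  expect_identical(predictVolume(m2, x1, x2), p1)
})

test_that("training in the overfit regime drives the L1 loss down", {
  les <- lesionSpec("osteoblastic", center = c(33, 33, 28), radiusMm = 8)
  spec <- phantomSpec(lesions = list(les), ctNoise = FALSE,
                      trabecularTexture = 0, seed = 7)
  case <- simulateCase(spec, "overfit", acquisitionParams(noiseSd = 0))
  cfg <- networkConfig(baseFilters = 8L)
  m0 <- buildNetwork(cfg, seed = 11)
  tc <- trainConfig(learningRate = 2e-3, epochs = 10L, batchSize = 2L,
                    patchesPerVolume = 24L, augment = FALSE, seed = 13L)
  tm <- train(m0, list(case), case, tc)
  h <- trainingHistory(tm)
  # noiseless phantom: no noise floor, so 0.05 normalized L1 is reachable
  expect_lt(min(h$trainLoss), 0.05)
  expect_lt(h$trainLoss[nrow(h)], h$trainLoss[1])
})

test_that("LOOCV fold structure never leaks the test case", {
  cohort <- makeCohort(4, phantomSpec(shape = c(32, 32, 32)), seed = 31)
  cfg <- networkConfig(baseFilters = 2L, patchSize = 16L)
  tc <- trainConfig(learningRate = 1e-3, epochs = 1L, batchSize = 2L,
                    patchesPerVolume = 2L, seed = 8L)
  cv <- loocv(cohort, cfg, tc)
  expect_equal(nrow(cv$reports), 8)  # 4 cases x 2 regions
  ids <- vapply(cohort, caseId, character(1))
  tested <- vapply(cv$folds, `[[`, character(1), "testId")
  expect_setequal(tested, ids)
  for (f in cv$folds) {
    expect_false(f$testId %in% f$trainingIds)
    expect_false(f$testId == f$validationId)
    expect_length(f$trainingIds, 2)
  }
  expect_s3_class(cv$summary, "data.frame")
})
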
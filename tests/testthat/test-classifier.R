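test_that("the architecture matches the two-convolution design exactly", {
  sp <- modelSpec(18)
  sh <- layerShapes(sp)
  expect_equal(sh, list(conv1 = 148L, pool1 = 74L, conv2 = 72L,
                        pool2 = 36L, flatten = 1152L))
  expect_equal(sp@conv1Kernels, 16L)
  expect_equal(sp@conv2Kernels, 32L)
  expect_equal(sp@kernelSize, 3L)
  expect_equal(sp@poolSize, 2L)
  expect_equal(sp@denseUnits, 100L)
  expect_equal(sp@dropoutRate, 0.2)

  m <- buildModel(sp)
  expect_equal(dim(m@weights$W1), c(3L, 16L))
  expect_equal(dim(m@weights$W2), c(48L, 32L))
  expect_equal(dim(m@weights$W3), c(1152L, 100L))
  expect_equal(dim(m@weights$W4), c(100L, 18L))

  expect_error(layerShapes(modelSpec(5, inputLen = 6)), "too short")
})

test_that("parameter count equals the layer-wise closed form", {
  for (N in c(2L, 18L, 90L, 218L)) {
    expected <- (3 * 1 + 1) * 16 + (3 * 16 + 1) * 32 +
      (1152 + 1) * 100 + (100 + 1) * N
    expect_equal(countParameters(modelSpec(N)), expected)
  }
  expect_equal(countParameters(modelSpec(18)), 118750)
})

test_that("softmax output is a proper probability over the label set", {
  m <- buildModel(modelSpec(6), seed = 2)
  m@labelOrder <- sprintf("s%d", 1:6)
  set.seed(1)
  p <- predictProba(m, matrix(rnorm(4 * 150), 4, 150))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  x1 <- matrix(rnorm(150), 1, 150)
  expect_identical(predictLabels(m, x1),
                   m@labelOrder[which.max(predictProba(m, x1))])
  # zeroed head -> exactly uniform probabilities -> lowest-index tie rule
  m@weights$W4[] <- 0; m@weights$b4[] <- 0
  p0 <- predictProba(m, matrix(rnorm(150), 1, 150))
  expect_equal(as.numeric(p0), rep(1 / 6, 6))
  expect_identical(predictLabels(m, matrix(rnorm(150), 1, 150)), "s1")

  expect_error(predictProba(m, matrix(0, 1, 100)), "length")
})

test_that("training separates well-separated classes and is reproducible", {
  ds <- mergeDatasets(list(syntheticBeatClass("a", 50, 1, seed = 1),
                           syntheticBeatClass("b", 50, 3, seed = 2)))
  sp <- splitDataset(ds, c(0.6, 0.2, 0.2), TRUE, 1)
  cfg <- trainConfig(maxEpochs = 30, seed = 4)
  fit <- trainClassifier(modelSpec(2), sp$train, sp$val, cfg)
  expect_equal(fit@history$acc[nrow(fit@history)], 1.0)
  expect_identical(labelOrder(fit), c("a", "b"))

  fit2 <- trainClassifier(modelSpec(2), sp$train, sp$val, cfg)
  expect_identical(fit@history$valLoss, fit2@history$valLoss)
  expect_identical(fit@weights, fit2@weights)

  pred <- predict(fit, sp$test, type = "class")
  expect_identical(pred,
                   labelOrder(fit)[max.col(predict(fit, sp$test, type = "prob"),
                                           ties.method = "first")])
  expect_gte(mean(pred == beatLabels(sp$test)), 0.95)
})

test_that("early stopping restores the best weights within patience", {
  ds <- mergeDatasets(list(syntheticBeatClass("a", 24, 1, noiseSd = 0.6, seed = 5),
                           syntheticBeatClass("b", 24, 1.2, noiseSd = 0.6, seed = 6)))
  sp <- splitDataset(ds, c(0.6, 0.2, 0.2), TRUE, 2)
  cfg <- trainConfig(maxEpochs = 200, patience = 5, seed = 8)
  fit <- trainClassifier(modelSpec(2), sp$train, sp$val, cfg)
  h <- fit@history
  best <- which.min(h$valLoss)
  expect_lte(nrow(h), best + cfg$patience)
})

test_that("closed-set contract: validation labels must be trainable", {
  tr <- syntheticBeatClass("a", 10, 1, seed = 1)
  tr2 <- mergeDatasets(list(tr, syntheticBeatClass("b", 10, 2, seed = 2)))
  va <- syntheticBeatClass("c", 4, 3, seed = 3)
  expect_error(trainClassifier(modelSpec(2), tr2, va,
                               trainConfig(maxEpochs = 1)), "absent")
})
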
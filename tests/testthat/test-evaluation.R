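test_that("confusion matrix counts true/predicted pairs", {
  cm <- confusionMatrix(c("0", "0", "1", "1"), c("0", "1", "1", "1"),
                        c("0", "1"))
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 2L), 2, 2))

  y <- c("a", "b", "a")
  expect_true(all(confusionMatrix(y, y, c("a", "b")) ==
                    diag(c(2L, 1L))))
  expect_true(all(confusionMatrix(character(0), character(0),
                                  c("a", "b")) == 0L))
  expect_error(confusionMatrix("a", "z", c("a", "b")), "unknown")
  expect_error(confusionMatrix(c("a", "a"), "a", c("a")), "equal length")
})

test_that("per-class metrics follow the one-vs-rest definitions", {
  cm <- matrix(c(1L, 0L, 1L, 2L), 2, 2,
               dimnames = list(c("c0", "c1"), c("c0", "c1")))
  pc <- perClassMetrics(cm)
  expect_equal(pc$precision, c(1, 2 / 3))
  expect_equal(pc$sensitivity, c(0.5, 1))
  expect_equal(pc$f1, c(2 / 3, 0.8))
  expect_equal(pc$TP + pc$FP + pc$TN + pc$FN, rep(4L, 2))

  diag3 <- diag(c(3L, 2L, 4L))
  dimnames(diag3) <- list(letters[1:3], letters[1:3])
  pcd <- perClassMetrics(diag3)
  expect_true(all(pcd[, c("precision", "sensitivity", "f1")] == 1))

  # class never present and never predicted: 0/0 convention = 0
  cm0 <- matrix(c(5L, 0L, 0L, 0L), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  pc0 <- perClassMetrics(cm0)
  expect_equal(unlist(pc0[2, c("precision", "sensitivity", "f1")]),
               c(precision = 0, sensitivity = 0, f1 = 0))
})

test_that("overall accuracy is the trace over the total", {
  cm <- matrix(c(1L, 0L, 1L, 2L), 2, 2)
  expect_equal(overallAccuracy(cm), 0.75)
  expect_equal(overallAccuracy(diag(c(2L, 3L))), 1.0)
  expect_equal(overallAccuracy(matrix(c(0L, 2L, 2L, 0L), 2, 2)), 0.0)
  expect_error(overallAccuracy(matrix(0L, 2, 2)), "empty")
})

test_that("macro averages weight every class equally", {
  rep1 <- evaluatePredictions(c("0", "0", "1", "1"), c("0", "1", "1", "1"),
                              c("0", "1"))
  expect_equal(accuracy(rep1), 0.75)
  expect_equal(rep1@macroPrecision, 5 / 6)
  expect_equal(rep1@macroSensitivity, 0.75)
  expect_equal(macroF1(rep1), (2 / 3 + 0.8) / 2)

  perfect <- evaluatePredictions(rep(letters[1:4], 5), rep(letters[1:4], 5),
                                 letters[1:4])
  expect_equal(c(accuracy(perfect), perfect@macroPrecision,
                 perfect@macroSensitivity, macroF1(perfect)),
               rep(1, 4))

  # label-order permutation leaves all summary metrics unchanged
  set.seed(9)
  yt <- sample(letters[1:5], 60, replace = TRUE)
  yp <- sample(letters[1:5], 60, replace = TRUE)
  r1 <- evaluatePredictions(yt, yp, letters[1:5])
  r2 <- evaluatePredictions(yt, yp, rev(letters[1:5]))
  expect_equal(accuracy(r1), accuracy(r2))
  expect_equal(macroF1(r1), macroF1(r2))
  expect_equal(r1@macroPrecision, r2@macroPrecision)

  # accuracy identity: sum of per-class TP over total
  pc <- perClassMetrics(r1@confusion)
  expect_equal(accuracy(r1), sum(pc$TP) / sum(r1@confusion))
})

test_that("evaluation agrees with a brute-force pair-scan oracle", {
  set.seed(17)
  for (i in 1:200) {
    k <- sample(2:25, 1)
    n <- sample(10:200, 1)
    labels <- sprintf("s%02d", 1:k)
    yt <- sample(labels, n, replace = TRUE)
    yp <- sample(labels, n, replace = TRUE)
    r <- suppressWarnings(evaluatePredictions(yt, yp, labels))
    o <- oracleMetrics(yt, yp, labels)
    expect_equal(unname(r@confusion), o$cm)
    expect_equal(accuracy(r), o$accuracy, tolerance = 1e-12)
    expect_equal(r@macroPrecision, o$macroPrecision, tolerance = 1e-12)
    expect_equal(r@macroSensitivity, o$macroSensitivity, tolerance = 1e-12)
    expect_equal(macroF1(r), o$macroF1, tolerance = 1e-12)
  }
})
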
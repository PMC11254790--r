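test_that("subject sampling is deterministic and honors point ranges", {
  expect_identical(sampleSubject(12)@waves, sampleSubject(12)@waves)

  pt <- list(
    P = list(center = c(-160, -160), amplitude = c(0.1, 0.1), width = c(20, 20)),
    Q = list(center = c(-25, -25), amplitude = c(-0.1, -0.1), width = c(9, 9)),
    R = list(center = c(0, 0), amplitude = c(1.2, 1.2), width = c(10, 10)),
    S = list(center = c(30, 30), amplitude = c(-0.2, -0.2), width = c(10, 10)),
    T = list(center = c(250, 250), amplitude = c(0.3, 0.3), width = c(45, 45))
  )
  tpl <- sampleSubject(3, ranges = pt)
  expect_equal(tpl@waves$center, c(-160, -25, 0, 30, 250))
  expect_equal(tpl@waves$amplitude, c(0.1, -0.1, 1.2, -0.2, 0.3))
  expect_equal(tpl@waves$width, c(20, 9, 10, 10, 45))

  bad <- pt
  bad$Q$center <- c(-300, -300)  # overlaps/precedes the P range
  expect_error(sampleSubject(3, ranges = bad), "overlap")
})

test_that("distinct seeds give morphologically distinct subjects", {
  beats <- lapply(1:50, function(s)
    renderBeat(sampleSubject(s), rr = 820, fsHz = 250))
  d <- as.matrix(dist(do.call(rbind, beats)))
  expect_true(all(d[upper.tri(d)] > 0))
})

test_that("renderBeat places waves and sizes the vector correctly", {
  onlyR <- sampleSubject(1)
  onlyR@waves$amplitude <- c(0, 0, 1.0, 0, 0)
  onlyR@waves$center <- c(-160, -25, 0, 30, 250)
  b <- renderBeat(onlyR, 800, 250)
  expect_equal(length(b), 200)
  expect_equal(max(b), 1.0, tolerance = 1e-9)
  expect_equal(which.max(b), 1L)  # R center at the segment start

  zero <- onlyR
  zero@waves$amplitude <- rep(0, 5)
  expect_equal(renderBeat(zero, 800, 250), rep(0, 200))

  expect_equal(length(renderBeat(sampleSubject(2), 800, 250)), 200)
  expect_error(renderBeat(sampleSubject(2), 100, 250), "span")
})

test_that("generated records have exact ground truth and are reproducible", {
  tpl <- sampleSubject(4)
  phys <- subjectPhysiology(1000, 0, 400)
  rec <- generateRecord(tpl, phys, noiseSpec(0, 0.25, 0, 50, 0),
                        duration = 10, fsHz = 250, seed = 5)
  expect_equal(unique(diff(trueRPeaks(rec))), 250)
  expect_true(abs(length(trueRPeaks(rec)) - 10) <= 1)

  rec2 <- generateRecord(tpl, phys, noiseSpec(0, 0.25, 0, 50, 0),
                         duration = 10, fsHz = 250, seed = 5)
  expect_identical(samples(rec), samples(rec2))

  # every true R index is a local max of the noiseless signal within +-1
  noisy <- generateRecord(tpl, subjectPhysiology(), noiseSpec(0, 0.25, 0, 50, 0),
                          duration = 30, fsHz = 500, seed = 6)
  x <- samples(noisy)
  n <- length(x)
  for (i in trueRPeaks(noisy)) {
    wide <- x[max(1, i - 9):min(n, i + 11)]        # +-10 samples, 0-based i
    narrow <- x[max(1, i):min(n, i + 2)]           # +-1 sample
    expect_gte(max(narrow), max(wide) - 1e-9)
  }
})

test_that("artifact injection perturbs exactly the reported intervals", {
  rec <- cleanRecord(seed = 9, meanRR = 800, duration = 40)
  expect_identical(injectArtifacts(rec, count = 0), rec)
  expect_error(injectArtifacts(rec, kinds = "flatline", count = 1), "unknown")

  dropped <- injectArtifacts(rec, "dropped_beat", count = 1, seed = 2)
  rrNominal <- 800
  expect_equal(sum(abs(dropped@rrMs - 2 * rrNominal) < 1), 1)
  expect_equal(sum(abs(dropped@rrMs - rrNominal) < 1),
               length(dropped@rrMs) - 1)

  again <- injectArtifacts(rec, "dropped_beat", count = 1, seed = 2)
  expect_identical(samples(dropped), samples(again))

  mixed <- injectArtifacts(rec, c("ectopic_short_rr", "dropped_beat"),
                           count = 4, seed = 3)
  phys <- mixed@physiology
  dev <- abs(mixed@rrMs[mixed@perturbed] - phys$meanRR)
  expect_true(all(dev > 3 * phys$sdnn + 0.1 * phys$meanRR))
  expect_length(mixed@perturbed, 4)
})

test_that("cohorts meet requested beat counts with distinct subjects", {
  co <- generateCohort(3, c(20, 40, 60), seed = 8)
  expect_length(co, 3)
  counts <- vapply(co, function(r) length(trueRPeaks(r)), integer(1))
  expect_true(all(counts >= c(20, 40, 60)))
  ids <- vapply(co, subjectId, character(1))
  expect_false(anyDuplicated(ids) > 0)

  co50 <- generateCohort(2, function(i) 50, seed = 8)
  expect_true(all(vapply(co50, function(r) length(trueRPeaks(r)), integer(1)) >= 50))
})

test_that("inter-subject morphology distance exceeds intra-subject noise", {
  # separability in the beat domain the classifier sees (after denoising and
  # fixed-length clipping) is what makes closed-set identification feasible
  centroids <- matrix(0, 20, 150)
  intra <- numeric(20)
  for (s in 1:20) {
    tpl <- sampleSubject(s)
    rec <- generateRecord(tpl, subjectPhysiology(820, 0, 400), noiseSpec(),
                          duration = 25, fsHz = 500, seed = s)
    ds <- suppressMessages(segmentRecord(preprocessRecord(rec), quiet = TRUE))
    B <- beatMatrix(ds)
    centroids[s, ] <- colMeans(B)
    d <- as.matrix(dist(B))
    intra[s] <- mean(d[upper.tri(d)])
  }
  inter <- as.matrix(dist(centroids))
  expect_gt(mean(inter[upper.tri(inter)]), mean(intra))
})
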
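test_that("RR lengths are consecutive peak differences", {
  pk <- function(i) new("RPeakList", indices = as.integer(i), fs = 250)
  expect_equal(rrLengths(pk(c(100, 300, 520))), c(200, 220))
  expect_equal(rrLengths(pk(42)), numeric(0))
  expect_equal(rrLengths(pk(integer(0))), numeric(0))
  expect_equal(rrLengths(pk(seq(0, 2500, by = 250))), rep(250, 10))
})

test_that("reference RR selection picks the values nearest the median", {
  cfg <- segmentationConfig()
  expect_equal(selectReferenceRR(rep(200, 8), cfg), rep(200, 8))
  expect_equal(selectReferenceRR(c(rep(200, 8), 400, 90), cfg), rep(200, 8))

  rr <- c(196, 198, 200, 202, 204, 196, 198, 206, 400)
  # brute-force oracle: rank all values by |rr - median|, earliest first
  med <- median(rr)
  ord <- order(abs(rr - med), seq_along(rr))
  expect_equal(selectReferenceRR(rr, cfg), rr[sort(ord[1:8])])
  expect_equal(selectReferenceRR(rr, cfg), rr[1:8])  # outlier excluded

  first8 <- segmentationConfig(refRule = "first-k")
  expect_equal(selectReferenceRR(rr, first8), rr[1:8])
  expect_error(selectReferenceRR(rep(200, 7), cfg), "rejected")
})

test_that("threshold statistics follow the mean +/- population sd rule", {
  s0 <- computeThresholds(rep(200, 8))
  expect_equal(c(s0@mu, s0@sigma, s0@th1, s0@th2), c(200, 0, 200, 200))

  worked <- computeThresholds(c(196, 198, 200, 202, 204, 196, 198, 206))
  expect_equal(worked@mu, 200)
  expect_equal(worked@sigma, sqrt(12))       # population divisor N = 8
  expect_equal(worked@th1, 200 - sqrt(12), tolerance = 1e-12)
  expect_equal(worked@th2, 200 + sqrt(12), tolerance = 1e-12)

  set.seed(5)
  for (i in 1:20) {
    st <- computeThresholds(sample(150:250, 8, replace = TRUE))
    expect_equal(st@th2 - st@th1, 2 * st@sigma, tolerance = 1e-12)
  }
  expect_error(computeThresholds(rep(200, 7)), "exactly 8")
})

test_that("clipping interpolates retained segments onto 150 samples", {
  mkRec <- function(x) new("EcgRecord", samples = x, fs = 250,
                           subjectId = "s1", recordId = "r1")
  mkPk <- function(i) new("RPeakList", indices = as.integer(i), fs = 250)

  # segment already 150 long: values pass through unchanged
  x <- c(rnorm(150), rnorm(100))
  st <- computeThresholds(rep(150, 8))
  ds <- clipBeats(mkRec(x), mkPk(c(0, 150)), st)
  expect_equal(as.numeric(beatMatrix(ds)[1, ]), x[1:150])

  # linear ramp: linear interpolation is exact
  ramp <- seq(0, 1, length.out = 200)
  st2 <- computeThresholds(rep(200, 8))
  ds2 <- clipBeats(mkRec(c(ramp, rnorm(50))), mkPk(c(0, 200)), st2)
  b <- as.numeric(beatMatrix(ds2)[1, ])
  expect_lt(max(abs(b - seq(0, ramp[200], length.out = 150))), 1e-9)
  expect_equal(b[1], ramp[1])     # endpoint preservation
  expect_equal(b[150], ramp[200])
  expect_false(is.unsorted(b))    # monotone time mapping on monotone data

  # only RR inside [th1, th2] are emitted
  stW <- computeThresholds(c(196, 198, 200, 202, 204, 196, 198, 206))
  peaks <- mkPk(cumsum(c(0, 195, 200, 204)))
  dsW <- clipBeats(mkRec(rnorm(650)), peaks, stW)
  expect_equal(nBeats(dsW), 1L)
  expect_equal(dsW@rrSamples, 200)
})

test_that("detector finds every beat of a clean record and nothing else", {
  rec <- cleanRecord(seed = 21, meanRR = 1000, duration = 60, sdnn = 30)
  pp <- preprocessRecord(rec)
  pk <- detectRPeaks(pp)
  m <- matchPeaks(rPeakIndices(pk), trueRPeaks(pp), tol = 10)  # +-40 ms
  expect_equal(m$fp, 0L)
  expect_equal(m$fn, 0L)

  flat <- new("EcgRecord", samples = rep(0, 2500), fs = 250,
              subjectId = "s", recordId = "r")
  expect_length(rPeakIndices(detectRPeaks(flat)), 0L)

  short <- new("EcgRecord", samples = rnorm(300), fs = 250,
               subjectId = "s", recordId = "r")
  expect_error(detectRPeaks(short), "2 s")
})

test_that("a dropped beat does not make search-back invent a peak", {
  rec <- cleanRecord(seed = 22, meanRR = 800, duration = 50)
  gap <- injectArtifacts(rec, "dropped_beat", count = 1, seed = 4)
  pp <- preprocessRecord(gap)
  det <- rPeakIndices(detectRPeaks(pp))
  truth <- trueRPeaks(pp)
  # every detection corresponds to a true R peak (no hallucinated peak in
  # the gap); the detected set is a subset of the truth
  err <- vapply(det, function(d) min(abs(truth - d)), numeric(1))
  expect_true(all(err <= 10))
  expect_lte(length(det), length(truth))
})

test_that("segmentRecord composes the stages and logs rejections", {
  rec <- cleanRecord(seed = 23, meanRR = 800, duration = 42)  # ~50 beats
  nTrue <- length(trueRPeaks(rec))
  ds <- suppressMessages(segmentRecord(preprocessRecord(rec), quiet = TRUE))
  expect_true(abs(nBeats(ds) - (nTrue - 1)) <= 1)
  expect_true(all(ncol(beatMatrix(ds)) == 150))
  expect_true(all(beatLabels(ds) == subjectId(rec)))

  # injected aberrant RR pairs are absent from the output
  art <- injectArtifacts(rec, c("ectopic_short_rr", "dropped_beat"),
                         count = 5, seed = 9)
  ppA <- preprocessRecord(art)
  dsA <- suppressMessages(segmentRecord(ppA, quiet = TRUE))
  aberrant <- art@rrMs[art@perturbed] * 250 / 1000   # samples at 250 Hz
  for (ab in aberrant)
    expect_false(any(abs(dsA@rrSamples - ab) < 3))

  # every emitted beat's RR lies inside the record's retention band
  pk <- detectRPeaks(ppA)
  rr <- rrLengths(pk)
  st <- computeThresholds(selectReferenceRR(rr))
  expect_true(all(dsA@rrSamples >= st@th1 & dsA@rrSamples <= st@th2))

  flat <- new("EcgRecord", samples = rep(0, 5000), fs = 250,
              subjectId = "s", recordId = "r")
  expect_warning(dsF <- segmentRecord(flat, quiet = TRUE), "rejected")
  expect_equal(nBeats(dsF), 0L)
})
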
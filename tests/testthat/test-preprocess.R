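test_that("resampling standardizes the rate and preserves duration", {
  rec <- new("EcgRecord", samples = sin(2 * pi * 5 * (0:1279) / 128),
             fs = 128, subjectId = "s", recordId = "r")
  out <- resampleRecord(rec, 250)
  expect_equal(fs(out), 250)
  expect_equal(length(samples(out)), 2500L)  # 10 s at 250 Hz

  at250 <- new("EcgRecord", samples = rnorm(500), fs = 250,
               subjectId = "s", recordId = "r")
  expect_identical(samples(resampleRecord(at250, 250)), samples(at250))
  expect_error(resampleRecord(at250, -1), "positive")
})

test_that("resampled sinusoid matches the analytic waveform", {
  t500 <- (0:4999) / 500
  rec <- new("EcgRecord", samples = sin(2 * pi * 5 * t500), fs = 500,
             subjectId = "s", recordId = "r")
  out <- resampleRecord(rec, 250)
  t250 <- (seq_along(samples(out)) - 1) / 250
  ref <- sin(2 * pi * 5 * t250)
  core <- 101:2400  # away from filter edge effects
  expect_gt(cor(samples(out)[core], ref[core]), 0.999)
})

test_that("band-pass removes DC and matches the analytic magnitude response", {
  cfg <- preprocessConfig()
  fsHz <- 250
  d <- bandpassDesign(cfg, fsHz)
  expect_equal(d$order, 3L)
  expect_equal(c(d$lowCut, d$highCut), c(0.6, 40))
  expect_error(bandpassDesign(preprocessConfig(highCut = 40), 60), "Nyquist")

  mkRec <- function(x) new("EcgRecord", samples = x, fs = fsHz,
                           subjectId = "s", recordId = "r")
  n <- 20 * fsHz
  t <- (0:(n - 1)) / fsHz
  core <- (5 * fsHz):(15 * fsHz)  # steady-state region

  dc <- bandpassRecord(mkRec(rep(1, n)), cfg)
  expect_lt(max(abs(samples(dc)[core])), 1e-3)

  ampAt <- function(freq) {
    y <- samples(bandpassRecord(mkRec(sin(2 * pi * freq * t)), cfg))
    sqrt(2 * mean(y[core]^2))
  }
  expect_equal(ampAt(10), filterMagnitude(d, 10), tolerance = 0.05)
  expect_equal(ampAt(60), filterMagnitude(d, 60), tolerance = 0.10)
  expect_lt(filterMagnitude(d, 60), 0.1)  # strong out-of-band attenuation
})

test_that("filtering is linear and zero-phase mode has no group delay", {
  cfg <- preprocessConfig()
  base <- resampleRecord(cleanRecord(seed = 11, duration = 20), 250)
  scaled <- initialize(base, samples = samples(base) * 3.5)
  a <- samples(bandpassRecord(base, cfg))
  b <- samples(bandpassRecord(scaled, cfg))
  expect_lt(max(abs(b - 3.5 * a)), 1e-9)

  # QRS peak positions before vs after zero-phase filtering
  raw <- resampleRecord(cleanRecord(seed = 12, duration = 30), 250)
  filt <- bandpassRecord(raw, cfg)
  for (i in trueRPeaks(raw)[3:20]) {
    win <- samples(filt)[(i - 4):(i + 6)]   # +-5 samples, 0-based index i
    expect_lte(abs(which.max(win) - 6), 1)
  }
})

test_that("preprocessing attenuates baseline wander by more than 90%", {
  wander <- noiseSpec(baselineAmp = 0.3, baselineFreq = 0.25,
                      powerlineAmp = 0, broadbandSd = 0)
  rec <- generateRecord(sampleSubject(13), subjectPhysiology(800, 0, 400),
                        wander, duration = 40, fsHz = 500, seed = 13)
  out <- preprocessRecord(rec)
  expect_equal(fs(out), 250)

  bandPower <- function(x, fsHz, lo, hi) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = fsHz), plot = FALSE,
                            taper = 0, detrend = FALSE)
    sum(sp$spec[sp$freq >= lo & sp$freq <= hi])
  }
  pBefore <- bandPower(samples(rec), 500, 0.1, 0.4)
  pAfter <- bandPower(samples(out), 250, 0.1, 0.4)
  expect_lt(pAfter, 0.1 * pBefore)

  # beat count survives the clean round trip
  clean <- cleanRecord(seed = 14, duration = 30)
  ds <- suppressMessages(segmentRecord(preprocessRecord(clean), quiet = TRUE))
  expect_equal(nBeats(ds), length(trueRPeaks(clean)) - 1, tolerance = 0.05)
})

test_that("config validation catches inconsistent cutoffs", {
  expect_error(preprocessConfig(lowCut = 50, highCut = 40), "cutoffs")
  expect_error(preprocessConfig(highCut = 200), "cutoffs")
  expect_error(preprocessConfig(order = 0), "order")
})
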
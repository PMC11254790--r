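#' Subject physiology for synthetic RR generation
#'
#' RR intervals are drawn from a normal law with mean \code{meanRR} and
#' standard deviation \code{sdnn}, truncated below at \code{rrFloor}
#' (redrawn until admissible). Occasional out-of-band RRs are supplied
#' separately by \code{\link{injectArtifacts}}.
#'
#' @param meanRR mean RR interval (ms).
#' @param sdnn standard deviation of RR (ms).
#' @param rrFloor minimum admissible RR (ms).
#' @return a validated physiology list.
#' @export
subjectPhysiology <- function(meanRR = 800, sdnn = 30, rrFloor = 400) {
  stopIf(meanRR <= 0, "meanRR must be positive")
  stopIf(sdnn < 0, "sdnn must be non-negative")
  stopIf(rrFloor <= 0 || rrFloor >= meanRR,
         "rrFloor must satisfy 0 < rrFloor < meanRR")
  list(meanRR = meanRR, sdnn = sdnn, rrFloor = rrFloor)
}

#' Additive noise specification
#'
#' The three noise classes of raw single-lead ECG emulated by the
#' generator: sinusoidal baseline wander, sinusoidal power-line
#' interference, and broadband (white) noise. Defaults are visibly
#' attenuated by the 0.6--40 Hz band-pass of \code{\link{bandpassRecord}}.
#'
#' @param baselineAmp baseline wander amplitude (mV).
#' @param baselineFreq baseline wander frequency (Hz).
#' @param powerlineAmp power-line amplitude (mV).
#' @param powerlineFreq power-line frequency (Hz).
#' @param broadbandSd white-noise standard deviation (mV).
#' @return a validated noise list.
#' @export
noiseSpec <- function(baselineAmp = 0.1, baselineFreq = 0.25,
                      powerlineAmp = 0.05, powerlineFreq = 50,
                      broadbandSd = 0.02) {
  stopIf(any(c(baselineAmp, powerlineAmp, broadbandSd) < 0),
         "noise amplitudes must be non-negative")
  stopIf(any(c(baselineFreq, powerlineFreq) <= 0),
         "noise frequencies must be positive")
  list(baselineAmp = baselineAmp, baselineFreq = baselineFreq,
       powerlineAmp = powerlineAmp, powerlineFreq = powerlineFreq,
       broadbandSd = broadbandSd)
}

zeroNoise <- function() noiseSpec(0, 0.25, 0, 50, 0)

#' Default per-wave sampling ranges
#'
#' Intervals (in ms for centers and widths, mV for amplitudes) from which
#' \code{\link{sampleSubject}} draws subject-specific P-QRS-T morphology.
#' The R center is pinned at 0 (the beat fiducial); P and Q have negative
#' offsets, i.e. they precede the R peak they belong to.
#'
#' @return a named list of per-wave \code{center}, \code{amplitude} and
#'   \code{width} intervals.
#' @export
defaultWaveRanges <- function() {
  list(
    P = list(center = c(-200, -140), amplitude = c(0.08, 0.18), width = c(18, 28)),
    Q = list(center = c(-35, -20),   amplitude = c(-0.15, -0.05), width = c(7, 12)),
    R = list(center = c(0, 0),       amplitude = c(0.8, 1.6),   width = c(8, 13)),
    S = list(center = c(20, 40),     amplitude = c(-0.30, -0.10), width = c(8, 13)),
    T = list(center = c(200, 300),   amplitude = c(0.20, 0.45), width = c(35, 60))
  )
}

#' Sample a subject morphology template
#'
#' Draws one P-QRS-T Gaussian-sum template uniformly from the given
#' per-wave parameter intervals. Deterministic for a fixed seed.
#'
#' @param seed integer seed.
#' @param ranges per-wave parameter intervals (see
#'   \code{\link{defaultWaveRanges}}); a zero-width interval pins the
#'   parameter to that point value.
#' @param subjectId subject identifier attached to the template.
#' @return a \linkS4class{SubjectTemplate}.
#' @export
sampleSubject <- function(seed, ranges = defaultWaveRanges(),
                          subjectId = sprintf("S%04d", seed %% 10000L)) {
  waveNames <- c("P", "Q", "R", "S", "T")
  stopIf(!identical(names(ranges), waveNames),
         "ranges must be named P, Q, R, S, T in order")
  for (w in waveNames) {
    r <- ranges[[w]]
    stopIf(!all(c("center", "amplitude", "width") %in% names(r)),
           "range for wave %s must give center, amplitude, width", w)
    stopIf(r$center[1] > r$center[2] || r$amplitude[1] > r$amplitude[2] ||
             r$width[1] > r$width[2],
           "interval bounds for wave %s must be ordered", w)
  }
  # physiological ordering of the center intervals: P < Q < R < S < T
  hi <- vapply(ranges, function(r) r$center[2], numeric(1))
  lo <- vapply(ranges, function(r) r$center[1], numeric(1))
  stopIf(any(hi[-5] >= lo[-1]), "wave center ranges must not overlap (P<Q<R<S<T)")

  draw <- function(iv) stats::runif(1, iv[1], iv[2])
  waves <- withSeed(seed, {
    do.call(rbind, lapply(waveNames, function(w) {
      r <- ranges[[w]]
      data.frame(wave = w, center = draw(r$center),
                 amplitude = draw(r$amplitude), width = draw(r$width),
                 stringsAsFactors = FALSE)
    }))
  })
  new("SubjectTemplate", subjectId = subjectId, waves = waves)
}

#' Time span covered by a template (ms)
#'
#' Distance between the earliest and latest 3-sigma extent of the five
#' waves; a single R-R interval must be at least this long for
#' \code{\link{renderBeat}} to place every wave.
#'
#' @param template a \linkS4class{SubjectTemplate}.
#' @return span in ms.
#' @export
templateSpan <- function(template) {
  w <- template@waves
  max(w$center + 3 * w$width) - min(w$center - 3 * w$width)
}

# Sum-of-Gaussians evaluation of the clean trace: one wave contribution per
# beat at absolute center rTime + wave offset. Each Gaussian is evaluated
# only on its +-6 sigma support.
renderSignal <- function(template, rTimesMs, nSamples, fsHz) {
  sig <- numeric(nSamples)
  w <- template@waves
  for (k in seq_len(nrow(w))) {
    sd_ms <- w$width[k]
    for (rt in rTimesMs) {
      c_ms <- rt + w$center[k]
      i0 <- max(0L, floor((c_ms - 6 * sd_ms) * fsHz / 1000))
      i1 <- min(nSamples - 1L, ceiling((c_ms + 6 * sd_ms) * fsHz / 1000))
      if (i1 < i0) next
      idx <- i0:i1
      t_ms <- idx * 1000 / fsHz
      sig[idx + 1L] <- sig[idx + 1L] +
        w$amplitude[k] * exp(-((t_ms - c_ms)^2) / (2 * sd_ms^2))
    }
  }
  sig
}

addNoise <- function(clean, noise, fsHz, noiseSeed, bursts = NULL) {
  n <- length(clean)
  t <- (seq_len(n) - 1L) / fsHz
  withSeed(noiseSeed, {
    ph <- stats::runif(2, 0, 2 * pi)
    out <- clean +
      noise$baselineAmp * sin(2 * pi * noise$baselineFreq * t + ph[1]) +
      noise$powerlineAmp * sin(2 * pi * noise$powerlineFreq * t + ph[2])
    if (noise$broadbandSd > 0)
      out <- out + stats::rnorm(n, 0, noise$broadbandSd)
    if (!is.null(bursts)) {
      for (b in bursts) {
        i0 <- max(1L, b$start + 1L)
        i1 <- min(n, b$start + b$len)
        if (i1 >= i0)
          out[i0:i1] <- out[i0:i1] + stats::rnorm(i1 - i0 + 1L, 0, b$sd)
      }
    }
    out
  })
}

#' Render one canonical beat
#'
#' Renders a single R-R segment of \code{round(rr * fs / 1000)} samples
#' with the R peak at sample 0. Waves with non-negative center offsets
#' (R, S, T) are placed at their offset; waves with negative offsets
#' (P, Q) precede the \emph{next} R peak and therefore appear near the end
#' of the segment, so that concatenated beats tile into a continuous trace.
#'
#' @param template a \linkS4class{SubjectTemplate}.
#' @param rr RR interval (ms); must be at least \code{templateSpan(template)}.
#' @param fsHz sampling rate (Hz).
#' @return numeric voltage vector (mV).
#' @export
renderBeat <- function(template, rr, fsHz) {
  stopIf(fsHz <= 0, "fsHz must be positive")
  stopIf(rr < templateSpan(template),
         "rr (%g ms) is shorter than the template span (%g ms)",
         rr, templateSpan(template))
  n <- round(rr * fsHz / 1000)
  w <- template@waves
  t_ms <- (seq_len(n) - 1L) * 1000 / fsHz
  sig <- numeric(n)
  for (k in seq_len(nrow(w))) {
    c_ms <- if (w$center[k] >= 0) w$center[k] else rr + w$center[k]
    sig <- sig + w$amplitude[k] * exp(-((t_ms - c_ms)^2) / (2 * w$width[k]^2))
  }
  sig
}

drawRR <- function(nBeats, phys) {
  if (phys$sdnn == 0) return(rep(phys$meanRR, nBeats))
  rr <- stats::rnorm(nBeats, phys$meanRR, phys$sdnn)
  while (any(bad <- rr < phys$rrFloor))
    rr[bad] <- stats::rnorm(sum(bad), phys$meanRR, phys$sdnn)
  rr
}

#' Generate one synthetic ECG record
#'
#' Places beats at cumulative RR positions drawn from the subject's
#' truncated-normal RR law, renders the Gaussian-sum morphology, adds
#' baseline wander, power-line and broadband noise, and records the true
#' R-peak sample indices. Bit-identical for a fixed seed.
#'
#' @param template a \linkS4class{SubjectTemplate}.
#' @param physiology see \code{\link{subjectPhysiology}}.
#' @param noise see \code{\link{noiseSpec}}.
#' @param duration record duration (s); must fit at least 2 beats.
#' @param fsHz sampling rate (Hz; default 500 so that the 250 Hz
#'   standardization stage is exercised).
#' @param seed integer seed.
#' @param recordId record identifier.
#' @return a \linkS4class{SyntheticEcgRecord}.
#' @export
generateRecord <- function(template, physiology = subjectPhysiology(),
                           noise = noiseSpec(), duration = 30, fsHz = 500,
                           seed = 1L,
                           recordId = paste0(template@subjectId, "_r1")) {
  stopIf(duration * 1000 < 2 * physiology$meanRR,
         "duration too short for at least 2 beats")
  nSamples <- as.integer(round(duration * fsHz))
  leadIn <- max(300, -min(template@waves$center - 3 * template@waves$width))
  nMax <- ceiling((duration * 1000 - leadIn) /
                    max(physiology$rrFloor, physiology$meanRR - 4 * physiology$sdnn)) + 2L
  rr <- withSeed(childSeed(seed, 1L), drawRR(nMax, physiology))
  rTimes <- leadIn + c(0, cumsum(rr))
  keep <- rTimes <= (nSamples - 1L) * 1000 / fsHz
  rTimes <- rTimes[keep]
  rr <- rr[seq_len(max(0L, length(rTimes) - 1L))]
  noiseSeed <- childSeed(seed, 2L)
  clean <- renderSignal(template, rTimes, nSamples, fsHz)
  sig <- addNoise(clean, noise, fsHz, noiseSeed)
  new("SyntheticEcgRecord",
      samples = sig, fs = fsHz,
      subjectId = template@subjectId, recordId = recordId,
      lead = "ECG1", session = "synthetic",
      trueRIndices = as.integer(round(rTimes * fsHz / 1000)),
      template = template, rrMs = rr, noise = noise,
      noiseSeed = noiseSeed, physiology = physiology,
      perturbed = integer())
}

# Re-render a synthetic record after its RR sequence was edited, keeping
# the original length, noise spec and noise seed.
rerenderRecord <- function(rec, rrMs, perturbed, bursts = NULL) {
  leadIn <- rec@trueRIndices[1] * 1000 / rec@fs
  rTimes <- leadIn + c(0, cumsum(rrMs))
  nSamples <- length(rec@samples)
  keep <- rTimes <= (nSamples - 1L) * 1000 / rec@fs
  rTimes <- rTimes[keep]
  rrMs <- rrMs[seq_len(max(0L, length(rTimes) - 1L))]
  clean <- renderSignal(rec@template, rTimes, nSamples, rec@fs)
  sig <- addNoise(clean, rec@noise, rec@fs, rec@noiseSeed, bursts)
  new("SyntheticEcgRecord",
      samples = sig, fs = rec@fs, subjectId = rec@subjectId,
      recordId = rec@recordId, lead = rec@lead, session = rec@session,
      trueRIndices = as.integer(round(rTimes * rec@fs / 1000)),
      template = rec@template, rrMs = rrMs, noise = rec@noise,
      noiseSeed = rec@noiseSeed, physiology = rec@physiology,
      perturbed = as.integer(perturbed[perturbed <= length(rrMs)]))
}

#' Inject RR artifacts into a synthetic record
#'
#' Produces records that exercise the rigid RR thresholding: a chosen
#' number of inter-beat intervals is perturbed so that their RR deviates
#' from the subject's mean RR by more than \code{3 * sdnn + 10\%} of the
#' mean. Kinds: \code{ectopic_short_rr} halves an interval (premature
#' beat), \code{dropped_beat} merges two intervals (missed beat, RR
#' doubles), \code{burst_noise} superimposes a high-amplitude noise burst
#' on the interval (true RR unchanged; detection-level RR is disturbed).
#' Perturbed interval indices (1-based into the RR sequence) are reported
#' in the \code{perturbed} slot.
#'
#' @param rec a \linkS4class{SyntheticEcgRecord}.
#' @param kinds character vector drawn from the three kinds above; recycled
#'   over \code{count}.
#' @param count number of intervals to perturb; must be smaller than the
#'   number of beats.
#' @param seed integer seed.
#' @return a new \linkS4class{SyntheticEcgRecord} with perturbations.
#' @export
injectArtifacts <- function(rec, kinds = "ectopic_short_rr", count = 1L,
                            seed = 1L) {
  allowed <- c("ectopic_short_rr", "dropped_beat", "burst_noise")
  bad <- setdiff(kinds, allowed)
  stopIf(length(bad) > 0, "unknown artifact kind(s): %s",
         paste(bad, collapse = ", "))
  if (count == 0L) return(rec)
  nInt <- length(rec@rrMs)
  stopIf(count >= length(rec@trueRIndices),
         "count must be smaller than the number of beats")
  # interior intervals, separated by at least one untouched interval
  eligible <- 2:(nInt - 1L)
  kinds <- rep_len(kinds, count)
  withSeed(childSeed(seed, 3L), {
    picked <- integer(0)
    pool <- eligible
    for (i in seq_len(count)) {
      stopIf(length(pool) == 0, "record too short for %d artifacts", count)
      j <- if (length(pool) == 1L) pool else sample(pool, 1L)
      picked <- c(picked, j)
      pool <- setdiff(pool, (j - 1L):(j + 1L))
    }
    rr <- rec@rrMs
    phys <- rec@physiology
    bursts <- list()
    drop <- integer(0)
    for (i in seq_len(count)) {
      j <- picked[i]
      if (kinds[i] == "ectopic_short_rr") {
        rr[j] <- max(phys$rrFloor * 0.8, phys$meanRR * 0.5)
      } else if (kinds[i] == "dropped_beat") {
        rr[j] <- rr[j] + rr[j + 1L]
        drop <- c(drop, j + 1L)
      } else { # burst_noise
        start <- rec@trueRIndices[j] + as.integer(0.3 * rr[j] * rec@fs / 1000)
        bursts[[length(bursts) + 1L]] <-
          list(start = start, len = as.integer(0.25 * rec@fs), sd = 0.6)
      }
    }
    if (length(drop)) {
      # removing each merged-away interval shifts later indices down by one;
      # picked intervals are pairwise non-adjacent, so none coincides with a
      # dropped index
      picked <- vapply(picked, function(j) j - sum(drop < j), integer(1))
      rr <- rr[-drop]
    }
    rerenderRecord(rec, rr, sort(unique(picked)),
                   if (length(bursts)) bursts else NULL)
  })
}

#' Generate a multi-subject synthetic cohort
#'
#' One record per subject, with subject-specific morphology and RR law
#' drawn from a seed-derived stream, sized so that each record contains at
#' least the requested number of beats before thresholding. Per-subject
#' beat counts may be imbalanced, mirroring real enrollment data where one
#' subject can contribute hundreds of beats and another a handful.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param beatsPerSubject integer vector (recycled), single integer, or
#'   function(i) returning the requested beat count for subject i.
#' @param fsHz sampling rate (Hz).
#' @param seed integer seed.
#' @param noise see \code{\link{noiseSpec}}.
#' @return list of \linkS4class{SyntheticEcgRecord}, one per subject.
#' @export
generateCohort <- function(nSubjects, beatsPerSubject = 50L, fsHz = 500,
                           seed = 1L, noise = noiseSpec()) {
  stopIf(nSubjects < 2, "nSubjects must be >= 2")
  counts <- if (is.function(beatsPerSubject))
    vapply(seq_len(nSubjects), beatsPerSubject, numeric(1))
  else rep_len(beatsPerSubject, nSubjects)
  stopIf(any(counts < 2), "each subject needs at least 2 beats")
  lapply(seq_len(nSubjects), function(i) {
    sid <- sprintf("S%02d", i)
    tpl <- sampleSubject(childSeed(seed, 10L + i), subjectId = sid)
    # highly regular resting rhythm: per-subject mean RR on the 4 ms grid
    # (one sample at 250 Hz) with zero sinus variability, so the rigid
    # mu +/- sigma band retains the regular beats; out-of-band RR values
    # are supplied by injectArtifacts
    phys <- withSeed(childSeed(seed, 100L + i), subjectPhysiology(
      meanRR = sample(seq(700, 1000, by = 4), 1L),
      sdnn = 0,
      rrFloor = 400
    ))
    dur <- (counts[i] + 3) * phys$meanRR / 1000
    generateRecord(tpl, phys, noise, duration = dur, fsHz = fsHz,
                   seed = childSeed(seed, 1000L + i),
                   recordId = paste0(sid, "_r1"))
  })
}
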
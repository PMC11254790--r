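#' Detect R peaks (Pan-Tompkins)
#'
#' Classic QRS detection pipeline: 5--15 Hz band-pass, five-point
#' derivative, pointwise squaring, 150 ms moving-window integration,
#' adaptive dual thresholds with running signal/noise peak estimates on
#' both the integrated and the band-passed signal, a 200 ms refractory
#' period, search-back with halved thresholds when no QRS is found within
#' 166\% of the running RR average, and T-wave rejection by slope
#' comparison for candidates within 360 ms of the previous QRS. Each
#' accepted fiducial is refined to the maximum of the input signal within
#' +/-40 ms. Window lengths scale with the sampling rate; the intended
#' input is a preprocessed 250 Hz record.
#'
#' @param rec a preprocessed \linkS4class{EcgRecord} (at least 2 s long).
#' @return an \linkS4class{RPeakList} of 0-based indices.
#' @export
detectRPeaks <- function(rec) {
  fsHz <- rec@fs
  x <- rec@samples
  n <- length(x)
  stopIf(n < 2 * fsHz, "record shorter than 2 s cannot be processed")
  emptyPeaks <- new("RPeakList", indices = integer(0), fs = fsHz)
  if (max(x) == min(x)) return(emptyPeaks)

  # stage 1: QRS-band band-pass (zero-phase to keep fiducials aligned)
  bt <- signal::butter(2, c(5, 15) / (fsHz / 2), type = "pass")
  f <- signal::filtfilt(bt, x)
  # stage 2: centered five-point derivative (1/8)[-1 -2 0 2 1]
  d <- as.numeric(stats::filter(f, c(1, 2, 0, -2, -1) / 8, sides = 2))
  d[is.na(d)] <- 0
  # stage 3-4: squaring and 150 ms moving-window integration
  wI <- max(1L, round(0.150 * fsHz))
  integ <- as.numeric(stats::filter(d^2, rep(1 / wI, wI), sides = 2))
  integ[is.na(integ)] <- 0
  if (max(integ) <= 0) return(emptyPeaks)

  # candidate fiducials: local maxima of the integrated signal
  up <- diff(integ) > 0
  cand <- which(c(FALSE, up) & c(!up, FALSE))
  cand <- cand[integ[cand] > 0]
  if (length(cand) == 0) return(emptyPeaks)

  refr <- round(0.200 * fsHz)
  twin <- round(0.360 * fsHz)
  wF <- round(0.075 * fsHz)
  peakF <- function(i) max(abs(f[max(1, i - wF):min(n, i + wF)]))
  slopeAt <- function(i) max(abs(d[max(1, i - wF):min(n, i + wF)]))

  # learning phase: first 2 s
  learn <- seq_len(round(2 * fsHz))
  spki <- 0.5 * max(integ[learn]); npki <- 0.5 * mean(integ[learn])
  spkf <- 0.5 * max(abs(f[learn])); npkf <- 0.5 * mean(abs(f[learn]))

  accepted <- integer(0)
  rr <- numeric(0)
  pending <- integer(0)   # candidates rejected since the last accepted QRS

  acceptPeak <- function(i, searchback = FALSE) {
    pi <- integ[i]; pf <- peakF(i)
    w <- if (searchback) 0.25 else 0.125
    spki <<- w * pi + (1 - w) * spki
    spkf <<- w * pf + (1 - w) * spkf
    if (length(accepted)) rr <<- c(rr, i - accepted[length(accepted)])
    accepted <<- c(accepted, i)
    pending <<- integer(0)
  }

  for (i in cand) {
    last <- if (length(accepted)) accepted[length(accepted)] else -Inf
    if (i - last < refr) next

    # search-back: no QRS within 166% of the running RR average
    if (length(rr) >= 2) {
      rrAvg <- mean(utils::tail(rr, 8))
      if (i - last > 1.66 * rrAvg && length(pending)) {
        thI <- npki + 0.25 * (spki - npki)
        thF <- npkf + 0.25 * (spkf - npkf)
        ok <- pending[pending - last >= refr &
                        integ[pending] > 0.5 * thI]
        ok <- ok[vapply(ok, peakF, numeric(1)) > 0.5 * thF]
        if (length(ok)) {
          best <- ok[which.max(integ[ok])]
          keepPending <- pending[pending > best]
          acceptPeak(best, searchback = TRUE)
          pending <- keepPending
          last <- best
          if (i - last < refr) next
        }
      }
    }

    thI <- npki + 0.25 * (spki - npki)
    thF <- npkf + 0.25 * (spkf - npkf)
    pi <- integ[i]; pf <- peakF(i)
    isQrs <- pi > thI && pf > thF
    if (isQrs && is.finite(last) && i - last < twin) {
      # T-wave test: slope markedly below the previous QRS slope
      if (slopeAt(i) < 0.5 * slopeAt(last)) isQrs <- FALSE
    }
    if (isQrs) {
      acceptPeak(i)
    } else {
      npki <- 0.125 * pi + 0.875 * npki
      npkf <- 0.125 * pf + 0.875 * npkf
      pending <- c(pending, i)
    }
  }
  if (length(accepted) == 0) return(emptyPeaks)

  # anchor each fiducial to the sharp QRS-band peak (the integrated-signal
  # maximum sits on a plateau), then refine to the local maximum of the
  # input signal within +/-40 ms
  wA <- round(0.080 * fsHz)
  wR <- round(0.040 * fsHz)
  refined <- vapply(accepted, function(i) {
    lo <- max(1, i - wA); hi <- min(n, i + wA)
    j <- lo + which.max(abs(f[lo:hi])) - 1L
    lo <- max(1, j - wR); hi <- min(n, j + wR)
    lo + which.max(x[lo:hi]) - 1L
  }, numeric(1))
  refined <- sort(unique(as.integer(refined - 1L)))  # to 0-based
  new("RPeakList", indices = refined, fs = fsHz)
}
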
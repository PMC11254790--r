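#' Preprocessing configuration
#'
#' Sampling-rate standardization and band-pass denoising settings: records
#' are resampled to \code{targetFs} (default 250 Hz) and filtered with an
#' order-\code{order} Butterworth band-pass between \code{lowCut} and
#' \code{highCut} (defaults 0.6 and 40 Hz), removing baseline wander below
#' the band and power-line/EMG noise above it. With \code{zeroPhase} the
#' filter is applied forward and backward (magnitude response squared, no
#' group delay), keeping beat morphology aligned for fiducial clipping.
#'
#' @param targetFs target sampling rate (Hz).
#' @param order filter order.
#' @param lowCut low cutoff (Hz).
#' @param highCut high cutoff (Hz).
#' @param zeroPhase logical; forward-backward filtering when TRUE.
#' @return a validated config list.
#' @export
preprocessConfig <- function(targetFs = 250, order = 3, lowCut = 0.6,
                             highCut = 40, zeroPhase = TRUE) {
  stopIf(targetFs <= 0, "targetFs must be positive")
  stopIf(order < 1, "order must be >= 1")
  stopIf(!(lowCut > 0 && lowCut < highCut && highCut < targetFs / 2),
         "cutoffs must satisfy 0 < lowCut < highCut < targetFs/2")
  list(targetFs = targetFs, order = as.integer(order),
       lowCut = lowCut, highCut = highCut, zeroPhase = isTRUE(zeroPhase))
}

# smallest integer ratio p/q equal to targetFs/fs (rates rounded to mHz)
rationalRate <- function(fsFrom, fsTo) {
  p <- round(fsTo * 1000)
  q <- round(fsFrom * 1000)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q)
  c(p = p / d, q = q / d)
}

# rational polyphase resampling: upsample by p (zero stuffing), linear-phase
# windowed-sinc low-pass at the narrower Nyquist, compensate the exact
# (N-1)/2 group delay, take every q-th sample
resamplePoly <- function(x, p, q) {
  if (p == q) return(x)
  n <- length(x)
  up <- numeric(n * p)
  up[seq(1L, n * p, by = p)] <- x
  m <- max(p, q)
  N <- 2L * 10L * m + 1L                    # odd tap count -> integer delay
  h <- p * signal::fir1(N - 1L, 1 / m)
  y <- signal::fftfilt(h, c(up, numeric(N)))
  y <- y[((N - 1L) / 2 + 1L):((N - 1L) / 2 + n * p)]
  y[seq(1L, n * p, by = q)]
}

#' Resample a record to a target rate
#'
#' Rational-factor polyphase resampling (exact 128 to 250 and 500 to 250 Hz
#' conversions without spectral imaging). Identity when the record is
#' already at the target rate.
#'
#' @param rec an \linkS4class{EcgRecord}.
#' @param targetFs target sampling rate (Hz).
#' @return the resampled \linkS4class{EcgRecord}.
#' @export
resampleRecord <- function(rec, targetFs = 250) {
  stopIf(targetFs <= 0, "targetFs must be positive")
  if (isTRUE(all.equal(rec@fs, targetFs))) return(rec)
  r <- rationalRate(rec@fs, targetFs)
  out <- resamplePoly(rec@samples, r["p"], r["q"])
  if (is(rec, "SyntheticEcgRecord")) {
    idx <- as.integer(round(rec@trueRIndices * targetFs / rec@fs))
    idx <- idx[idx < length(out)]
    initialize(rec, samples = as.numeric(out), fs = targetFs,
               trueRIndices = idx)
  } else {
    initialize(rec, samples = as.numeric(out), fs = targetFs)
  }
}

#' Design the band-pass filter for a record
#'
#' Exposes the designed Butterworth coefficients together with the exact
#' order and cutoffs used, so the design is inspectable.
#'
#' @param cfg a \code{\link{preprocessConfig}}.
#' @param fsHz sampling rate the filter is designed for.
#' @return list with elements \code{b}, \code{a}, \code{order},
#'   \code{lowCut}, \code{highCut}, \code{fs}, \code{zeroPhase}.
#' @export
bandpassDesign <- function(cfg, fsHz) {
  stopIf(cfg$highCut >= fsHz / 2, "highCut must be below the Nyquist rate")
  bt <- signal::butter(cfg$order, c(cfg$lowCut, cfg$highCut) / (fsHz / 2),
                       type = "pass")
  list(b = bt$b, a = bt$a, order = cfg$order, lowCut = cfg$lowCut,
       highCut = cfg$highCut, fs = fsHz, zeroPhase = cfg$zeroPhase)
}

#' Analytic magnitude response of a designed filter
#'
#' Evaluates |H(f)| of the designed digital filter at the given
#' frequencies; squared when the filter is applied zero-phase
#' (forward-backward).
#'
#' @param design a \code{\link{bandpassDesign}}.
#' @param freqHz frequencies (Hz).
#' @return numeric vector of magnitudes.
#' @export
filterMagnitude <- function(design, freqHz) {
  w <- 2 * pi * freqHz / design$fs
  z <- exp(1i * w)
  num <- vapply(z, function(zz) sum(design$b * zz^-(seq_along(design$b) - 1)),
                complex(1))
  den <- vapply(z, function(zz) sum(design$a * zz^-(seq_along(design$a) - 1)),
                complex(1))
  mag <- Mod(num / den)
  if (design$zeroPhase) mag^2 else mag
}

#' Band-pass filter a record
#'
#' @param rec an \linkS4class{EcgRecord}.
#' @param cfg a \code{\link{preprocessConfig}}.
#' @return the filtered \linkS4class{EcgRecord} (same length and rate).
#' @export
bandpassRecord <- function(rec, cfg = preprocessConfig()) {
  d <- bandpassDesign(cfg, rec@fs)
  x <- rec@samples
  y <- if (cfg$zeroPhase)
    signal::filtfilt(signal::Arma(b = d$b, a = d$a), x)
  else
    as.numeric(signal::filter(signal::Arma(b = d$b, a = d$a), x))
  initialize(rec, samples = as.numeric(y))
}

#' Standardize and denoise a record
#'
#' Composition used before segmentation: resample to the target rate, then
#' band-pass filter.
#'
#' @param rec an \linkS4class{EcgRecord}.
#' @param cfg a \code{\link{preprocessConfig}}.
#' @return the preprocessed \linkS4class{EcgRecord}.
#' @export
preprocessRecord <- function(rec, cfg = preprocessConfig()) {
  bandpassRecord(resampleRecord(rec, cfg$targetFs), cfg)
}
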
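#' Segmentation configuration
#'
#' Settings of the rigid RR thresholding and beat interpolation stage.
#' Eight reference RR lengths in the normal range are chosen per record;
#' the default \code{median-nearest} rule picks the eight RR values
#' closest to the record's median RR (robust to the very artifacts the
#' rule must exclude), with \code{first-k} available for sensitivity
#' analysis. Retention bounds are inclusive: only RR strictly below th1 or
#' strictly above th2 are discarded.
#'
#' @param beatLength output beat length in samples (default 150).
#' @param nRef number of reference RR lengths (default 8).
#' @param refRule \code{"median-nearest"} or \code{"first-k"}.
#' @param interp \code{"linear"} (exact on piecewise-linear data, no
#'   ringing) or \code{"cubic"}.
#' @param inclusiveBounds retain RR equal to a threshold (default TRUE).
#' @return a validated config list.
#' @export
segmentationConfig <- function(beatLength = 150L, nRef = 8L,
                               refRule = c("median-nearest", "first-k"),
                               interp = c("linear", "cubic"),
                               inclusiveBounds = TRUE) {
  stopIf(beatLength < 2, "beatLength must be >= 2")
  stopIf(nRef < 2, "nRef must be >= 2")
  list(beatLength = as.integer(beatLength), nRef = as.integer(nRef),
       refRule = match.arg(refRule), interp = match.arg(interp),
       inclusiveBounds = isTRUE(inclusiveBounds))
}

#' RR lengths between consecutive detected peaks
#'
#' @param peaks an \linkS4class{RPeakList}.
#' @return numeric vector of differences \code{x_i - x_(i-1)} in samples;
#'   empty when fewer than 2 peaks.
#' @export
rrLengths <- function(peaks) {
  if (length(peaks@indices) < 2L) return(numeric(0))
  as.numeric(diff(peaks@indices))
}

#' Select the reference RR lengths in the normal range
#'
#' Under the default \code{median-nearest} rule, returns the \code{nRef}
#' RR values with the smallest absolute distance to the median RR of the
#' record (ties broken by earliest occurrence), in their original order.
#' Under \code{first-k}, the first \code{nRef} values.
#'
#' @param rr numeric vector of RR lengths (samples).
#' @param cfg a \code{\link{segmentationConfig}}.
#' @return numeric vector of length \code{cfg$nRef}.
#' @export
selectReferenceRR <- function(rr, cfg = segmentationConfig()) {
  k <- cfg$nRef
  stopIf(length(rr) < k,
         "record rejected: %d RR intervals, need at least %d", length(rr), k)
  idx <- if (cfg$refRule == "first-k") seq_len(k) else {
    med <- stats::median(rr)
    sort(order(abs(rr - med), seq_along(rr))[seq_len(k)])
  }
  rr[idx]
}

#' Rigid-thresholding statistics from the reference RR lengths
#'
#' Mean and population standard deviation (divisor N = 8) of the eight
#' reference RR lengths; retention band \code{[mu - sigma, mu + sigma]}.
#'
#' @param rrRef the reference RR lengths (length 8 by default).
#' @param rrAll optionally, all RR lengths of the record (kept for
#'   reporting).
#' @param nRef expected reference count.
#' @return a \linkS4class{ThresholdStats}.
#' @export
computeThresholds <- function(rrRef, rrAll = rrRef, nRef = 8L) {
  stopIf(length(rrRef) != nRef,
         "expected exactly %d reference RR lengths, got %d",
         nRef, length(rrRef))
  mu <- mean(rrRef)
  sigma <- sqrt(mean((rrRef - mu)^2))
  new("ThresholdStats", rrAll = as.numeric(rrAll),
      rrRef = as.numeric(rrRef), mu = mu, sigma = sigma,
      th1 = mu - sigma, th2 = mu + sigma)
}

interpTo <- function(seg, L, method) {
  m <- length(seg)
  if (m == L) return(seg)
  xout <- seq(0, m - 1L, length.out = L)
  if (method == "cubic")
    stats::spline(x = 0:(m - 1L), y = seg, xout = xout)$y
  else
    stats::approx(x = 0:(m - 1L), y = seg, xout = xout)$y
}

#' Clip retained R-R segments into fixed-length beats
#'
#' For each consecutive peak pair whose RR lies inside the retention band,
#' the half-open segment \code{[x_(i-1), x_i)} is interpolated over
#' normalized time onto \code{beatLength} samples. Segments outside the
#' band produce nothing.
#'
#' @param rec the preprocessed \linkS4class{EcgRecord}.
#' @param peaks the detected \linkS4class{RPeakList}.
#' @param stats the record's \linkS4class{ThresholdStats}.
#' @param cfg a \code{\link{segmentationConfig}}.
#' @return a \linkS4class{BeatDataset} (possibly empty).
#' @export
clipBeats <- function(rec, peaks, stats, cfg = segmentationConfig()) {
  idx <- peaks@indices
  L <- cfg$beatLength
  rows <- list(); rrKeep <- numeric(0)
  if (length(idx) >= 2L) {
    rr <- diff(idx)
    keep <- if (cfg$inclusiveBounds)
      rr >= stats@th1 & rr <= stats@th2
    else
      rr > stats@th1 & rr < stats@th2
    for (i in which(keep)) {
      seg <- rec@samples[(idx[i] + 1L):idx[i + 1L]]  # [x_(i-1), x_i), 0-based
      rows[[length(rows) + 1L]] <- interpTo(seg, L, cfg$interp)
      rrKeep <- c(rrKeep, rr[i])
    }
  }
  if (length(rows) == 0)
    return(beatDataset(matrix(numeric(0), 0, L), character(0)))
  beatDataset(do.call(rbind, rows),
              rep(rec@subjectId, length(rows)),
              rep(rec@recordId, length(rows)),
              rrKeep)
}

#' Segment a record into fixed-length single heartbeats
#'
#' Composition of detection, RR differencing, reference selection,
#' threshold computation and clipping. Records with fewer than
#' \code{nRef} RR intervals yield zero beats with a warning. A per-record
#' log line reports the stage counts.
#'
#' @param rec the preprocessed \linkS4class{EcgRecord}.
#' @param cfg a \code{\link{segmentationConfig}}.
#' @param quiet suppress the per-record log line.
#' @return a \linkS4class{BeatDataset}.
#' @export
segmentRecord <- function(rec, cfg = segmentationConfig(), quiet = FALSE) {
  peaks <- detectRPeaks(rec)
  rr <- rrLengths(peaks)
  empty <- beatDataset(matrix(numeric(0), 0, cfg$beatLength), character(0))
  if (length(rr) < cfg$nRef) {
    warning(sprintf(
      "record '%s' rejected: only %d RR intervals (need %d); no beats emitted",
      rec@recordId, length(rr), cfg$nRef), call. = FALSE)
    return(empty)
  }
  stats <- computeThresholds(selectReferenceRR(rr, cfg), rr, cfg$nRef)
  ds <- clipBeats(rec, peaks, stats, cfg)
  if (!quiet)
    logMsg("record '%s': %d peaks, %d RR, %d retained, %d beats",
           rec@recordId, length(peaks@indices), length(rr),
           nBeats(ds), nBeats(ds))
  ds
}
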
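#' @import methods
NULL

#' Single-lead ECG record
#'
#' A sampled single-lead voltage trace in millivolts together with its
#' sampling rate and identity metadata. All sample indices in the package
#' are 0-based and intervals are half-open \code{[start, end)}.
#'
#' @slot samples numeric vector of voltages (mV).
#' @slot fs sampling rate in Hz.
#' @slot subjectId subject identifier.
#' @slot recordId record identifier.
#' @slot lead lead/channel name (e.g. \code{"ECG1"}, \code{"MLII"}).
#' @slot session free-form session tag.
#'
#' @exportClass EcgRecord
setClass("EcgRecord",
  representation(
    samples = "numeric",
    fs = "numeric",
    subjectId = "character",
    recordId = "character",
    lead = "character",
    session = "character"
  ),
  prototype(lead = "ECG1", session = "")
)

setValidity("EcgRecord", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@samples) == 0L)
    msg <- c(msg, "samples must be non-empty")
  if (anyNA(object@samples))
    msg <- c(msg, "samples must not contain NA/NaN")
  if (length(msg)) msg else TRUE
})

#' Subject beat-morphology template
#'
#' Five Gaussian wave descriptors (P, Q, R, S, T) positioned relative to the
#' R peak. Each wave has a center offset (ms, R at 0), a signed amplitude
#' (mV) and a Gaussian width (sigma, ms). Inter-individual differences in
#' these parameters are what make subjects separable.
#'
#' @slot subjectId subject identifier.
#' @slot waves data.frame with columns \code{wave} ("P","Q","R","S","T"),
#'   \code{center} (ms), \code{amplitude} (mV), \code{width} (ms).
#'
#' @exportClass SubjectTemplate
setClass("SubjectTemplate",
  representation(subjectId = "character", waves = "data.frame")
)

setValidity("SubjectTemplate", function(object) {
  w <- object@waves
  msg <- character()
  if (!identical(w$wave, c("P", "Q", "R", "S", "T")))
    msg <- c(msg, "waves must be exactly P, Q, R, S, T in order")
  if (nrow(w) == 5L) {
    if (is.unsorted(w$center, strictly = TRUE))
      msg <- c(msg, "wave centers must be strictly increasing (P<Q<R<S<T)")
    if (any(w$width <= 0))
      msg <- c(msg, "wave widths must be strictly positive")
    r_amp <- abs(w$amplitude[w$wave == "R"])
    if (any(w$amplitude != 0) &&
        any(abs(w$amplitude[w$wave != "R"]) >= r_amp))
      msg <- c(msg, "R amplitude must dominate all other waves in magnitude")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic ECG record with ground truth
#'
#' An \linkS4class{EcgRecord} generated from a known
#' \linkS4class{SubjectTemplate}, carrying the true R-peak sample indices
#' (0-based) and the generation state needed to re-render the trace
#' deterministically (RR sequence, noise specification and seed).
#'
#' @slot trueRIndices integer vector of true R-peak sample indices (0-based,
#'   strictly increasing).
#' @slot template the \linkS4class{SubjectTemplate} used for rendering.
#' @slot rrMs RR interval sequence (ms) between consecutive rendered beats.
#' @slot noise noise specification list (see \code{\link{noiseSpec}}).
#' @slot noiseSeed integer seed used for the noise realization.
#' @slot physiology physiology list (see \code{\link{subjectPhysiology}}).
#' @slot perturbed integer vector of RR interval indices (1-based into
#'   \code{rrMs}) altered by \code{\link{injectArtifacts}}.
#'
#' @exportClass SyntheticEcgRecord
setClass("SyntheticEcgRecord",
  contains = "EcgRecord",
  representation(
    trueRIndices = "integer",
    template = "SubjectTemplate",
    rrMs = "numeric",
    noise = "list",
    noiseSeed = "integer",
    physiology = "list",
    perturbed = "integer"
  ),
  prototype(perturbed = integer())
)

setValidity("SyntheticEcgRecord", function(object) {
  idx <- object@trueRIndices
  msg <- character()
  if (length(idx) && is.unsorted(idx, strictly = TRUE))
    msg <- c(msg, "trueRIndices must be strictly increasing")
  if (length(idx) && (min(idx) < 0L || max(idx) >= length(object@samples)))
    msg <- c(msg, "trueRIndices must lie within signal bounds")
  if (length(msg)) msg else TRUE
})

#' Detected R-peak positions
#'
#' @slot indices strictly increasing 0-based sample positions of detected
#'   R peaks in the (preprocessed) signal.
#' @slot fs sampling rate (Hz) of the signal the indices refer to.
#'
#' @exportClass RPeakList
setClass("RPeakList",
  representation(indices = "integer", fs = "numeric")
)

setValidity("RPeakList", function(object) {
  msg <- character()
  if (length(object@indices) && is.unsorted(object@indices, strictly = TRUE))
    msg <- c(msg, "indices must be strictly increasing")
  if (any(object@indices < 0L))
    msg <- c(msg, "indices must be non-negative")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Rigid RR-threshold statistics
#'
#' The statistics of the rigid length-thresholding rule: from all RR lengths
#' of a record, eight reference lengths in the normal range are selected;
#' their mean \code{mu} and population standard deviation \code{sigma}
#' define the retention band \code{[th1, th2] = [mu - sigma, mu + sigma]}.
#'
#' @slot rrAll all RR lengths (samples) of the record, in order.
#' @slot rrRef the eight reference RR lengths (samples).
#' @slot mu mean of \code{rrRef}.
#' @slot sigma population standard deviation (divisor N = 8) of \code{rrRef}.
#' @slot th1 lower threshold \code{mu - sigma}.
#' @slot th2 upper threshold \code{mu + sigma}.
#'
#' @exportClass ThresholdStats
setClass("ThresholdStats",
  representation(
    rrAll = "numeric", rrRef = "numeric",
    mu = "numeric", sigma = "numeric", th1 = "numeric", th2 = "numeric"
  )
)

setValidity("ThresholdStats", function(object) {
  msg <- character()
  if (length(object@rrRef) != 8L)
    msg <- c(msg, "rrRef must contain exactly 8 values")
  if (object@sigma < 0) msg <- c(msg, "sigma must be non-negative")
  if (abs(object@th1 - (object@mu - object@sigma)) > 1e-9)
    msg <- c(msg, "th1 must equal mu - sigma")
  if (abs(object@th2 - (object@mu + object@sigma)) > 1e-9)
    msg <- c(msg, "th2 must equal mu + sigma")
  if (length(msg)) msg else TRUE
})

#' Labeled fixed-length beat collection
#'
#' A matrix of fixed-length (by default 150-sample) interpolated R-R beats,
#' one beat per row, with a subject label and source record id per row.
#' \code{rrSamples} keeps each beat's original RR length (samples) before
#' interpolation; it is \code{NA} for beats read back from CSV, which does
#' not store it.
#'
#' @slot beats numeric matrix, rows = beats, columns = samples (mV).
#' @slot labels character vector of subject identifiers, one per row.
#' @slot recordIds character vector of source record identifiers per row.
#' @slot rrSamples numeric vector of original RR lengths per row (samples).
#'
#' @exportClass BeatDataset
setClass("BeatDataset",
  representation(
    beats = "matrix", labels = "character",
    recordIds = "character", rrSamples = "numeric"
  )
)

setValidity("BeatDataset", function(object) {
  n <- nrow(object@beats)
  msg <- character()
  if (length(object@labels) != n)
    msg <- c(msg, "labels length must equal beat row count")
  if (length(object@recordIds) != n)
    msg <- c(msg, "recordIds length must equal beat row count")
  if (length(object@rrSamples) != n)
    msg <- c(msg, "rrSamples length must equal beat row count")
  if (n > 0L && ncol(object@beats) < 2L)
    msg <- c(msg, "beats must have at least 2 sample columns")
  if (n > 0L && anyNA(object@beats))
    msg <- c(msg, "beat values must not contain NA")
  if (length(msg)) msg else TRUE
})

#' 1D-CNN architecture description
#'
#' The compact two-convolution architecture used for closed-set beat
#' identification: conv(16, 3) + ReLU, max-pool(2), conv(32, 3) + ReLU,
#' max-pool(2), flatten, dense(100) + ReLU, dropout(0.2), softmax output.
#'
#' @slot inputLen beat vector length (default 150).
#' @slot conv1Kernels number of kernels in the first convolution.
#' @slot conv2Kernels number of kernels in the second convolution.
#' @slot kernelSize convolution filter length.
#' @slot poolSize max-pooling window.
#' @slot denseUnits width of the fully connected layer.
#' @slot dropoutRate dropout fraction in [0, 1).
#' @slot nClasses number of enrolled subjects (output width).
#' @slot padding \code{"valid"} or \code{"same"}.
#'
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(
    inputLen = "integer", conv1Kernels = "integer", conv2Kernels = "integer",
    kernelSize = "integer", poolSize = "integer", denseUnits = "integer",
    dropoutRate = "numeric", nClasses = "integer", padding = "character"
  )
)

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  counts <- c(object@inputLen, object@conv1Kernels, object@conv2Kernels,
              object@kernelSize, object@poolSize, object@denseUnits)
  if (any(counts <= 0L)) msg <- c(msg, "all layer sizes must be positive")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (!object@padding %in% c("valid", "same"))
    msg <- c(msg, "padding must be 'valid' or 'same'")
  if (length(msg)) msg else TRUE
})

#' Fitted beat classifier
#'
#' @slot spec the \linkS4class{ModelSpec} of the architecture.
#' @slot weights list of weight arrays (opaque; layout is internal).
#' @slot labelOrder class-index-to-subject bijection (sorted subject ids).
#' @slot history per-epoch data.frame of train/validation loss and accuracy.
#'
#' @exportClass TrainedClassifier
setClass("TrainedClassifier",
  representation(
    spec = "ModelSpec", weights = "list",
    labelOrder = "character", history = "data.frame"
  )
)

setValidity("TrainedClassifier", function(object) {
  if (anyDuplicated(object@labelOrder))
    "labelOrder must be a bijection (no duplicated labels)" else TRUE
})

#' Multi-class evaluation report
#'
#' Confusion matrix (rows = true class, columns = predicted class), overall
#' accuracy (trace / total), and unweighted macro averages of the per-class
#' one-vs-rest precision, sensitivity and F1.
#'
#' @slot confusion integer confusion matrix with class labels as dimnames.
#' @slot accuracy overall accuracy in [0, 1].
#' @slot macroPrecision unweighted mean of per-class precision.
#' @slot macroSensitivity unweighted mean of per-class sensitivity (recall).
#' @slot macroF1 unweighted mean of per-class F1.
#' @slot perClass data.frame with per-class TP, FP, TN, FN, accuracy,
#'   precision, sensitivity, f1.
#'
#' @exportClass EvalReport
setClass("EvalReport",
  representation(
    confusion = "matrix", accuracy = "numeric",
    macroPrecision = "numeric", macroSensitivity = "numeric",
    macroF1 = "numeric", perClass = "data.frame"
  )
)

setValidity("EvalReport", function(object) {
  msg <- character()
  if (nrow(object@confusion) != ncol(object@confusion))
    msg <- c(msg, "confusion matrix must be square")
  if (any(object@confusion < 0))
    msg <- c(msg, "confusion counts must be non-negative")
  vals <- c(object@accuracy, object@macroPrecision,
            object@macroSensitivity, object@macroF1)
  if (any(vals < -1e-12 | vals > 1 + 1e-12))
    msg <- c(msg, "metrics must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
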
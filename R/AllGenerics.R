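#' Accessors for package classes
#'
#' Small accessor generics: \code{fs} returns the sampling rate (Hz),
#' \code{samples} the voltage vector (mV), \code{beatMatrix} the beats-by-
#' samples matrix, \code{beatLabels} the per-beat subject labels,
#' \code{nBeats} the number of beats, \code{trueRPeaks} the ground-truth
#' R indices of a synthetic record, and \code{labelOrder} the class-index
#' to subject mapping of a fitted classifier.
#'
#' @param object an object of one of the package's classes.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fs", function(object) standardGeneric("fs"))

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("recordId", function(object) standardGeneric("recordId"))

#' @rdname accessors
#' @export
setGeneric("beatMatrix", function(object) standardGeneric("beatMatrix"))

#' @rdname accessors
#' @export
setGeneric("beatLabels", function(object) standardGeneric("beatLabels"))

#' @rdname accessors
#' @export
setGeneric("nBeats", function(object) standardGeneric("nBeats"))

#' @rdname accessors
#' @export
setGeneric("trueRPeaks", function(object) standardGeneric("trueRPeaks"))

#' @rdname accessors
#' @export
setGeneric("labelOrder", function(object) standardGeneric("labelOrder"))

#' @rdname accessors
#' @export
setGeneric("rPeakIndices", function(object) standardGeneric("rPeakIndices"))

#' @rdname accessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))

#' @rdname accessors
#' @export
setGeneric("macroF1", function(object) standardGeneric("macroF1"))

#' @rdname accessors
setMethod("fs", "EcgRecord", function(object) object@fs)

#' @rdname accessors
setMethod("fs", "RPeakList", function(object) object@fs)

#' @rdname accessors
setMethod("samples", "EcgRecord", function(object) object@samples)

#' @rdname accessors
setMethod("subjectId", "EcgRecord", function(object) object@subjectId)

#' @rdname accessors
setMethod("subjectId", "SubjectTemplate", function(object) object@subjectId)

#' @rdname accessors
setMethod("recordId", "EcgRecord", function(object) object@recordId)

#' @rdname accessors
setMethod("beatMatrix", "BeatDataset", function(object) object@beats)

#' @rdname accessors
setMethod("beatLabels", "BeatDataset", function(object) object@labels)

#' @rdname accessors
setMethod("nBeats", "BeatDataset", function(object) nrow(object@beats))

#' @rdname accessors
setMethod("trueRPeaks", "SyntheticEcgRecord", function(object) object@trueRIndices)

#' @rdname accessors
setMethod("labelOrder", "TrainedClassifier", function(object) object@labelOrder)

#' @rdname accessors
setMethod("rPeakIndices", "RPeakList", function(object) object@indices)

#' @rdname accessors
setMethod("accuracy", "EvalReport", function(object) object@accuracy)

#' @rdname accessors
setMethod("macroF1", "EvalReport", function(object) object@macroF1)

setMethod("show", "EcgRecord", function(object) {
  cat(sprintf("%s record '%s' (subject '%s', lead %s)\n",
              class(object), object@recordId, object@subjectId, object@lead))
  cat(sprintf("  %d samples at %g Hz (%.1f s), range [%.3f, %.3f] mV\n",
              length(object@samples), object@fs,
              length(object@samples) / object@fs,
              min(object@samples), max(object@samples)))
  if (is(object, "SyntheticEcgRecord"))
    cat(sprintf("  %d true R peaks; %d perturbed RR intervals\n",
                length(object@trueRIndices), length(object@perturbed)))
  invisible(NULL)
})

setMethod("show", "SubjectTemplate", function(object) {
  cat(sprintf("SubjectTemplate '%s'\n", object@subjectId))
  print(object@waves, row.names = FALSE)
  invisible(NULL)
})

setMethod("show", "RPeakList", function(object) {
  cat(sprintf("RPeakList: %d peaks at %g Hz\n",
              length(object@indices), object@fs))
  invisible(NULL)
})

setMethod("show", "ThresholdStats", function(object) {
  cat(sprintf(
    "ThresholdStats: %d RR intervals; mu = %.3f, sigma = %.3f, band [%.3f, %.3f] samples\n",
    length(object@rrAll), object@mu, object@sigma, object@th1, object@th2))
  invisible(NULL)
})

setMethod("show", "BeatDataset", function(object) {
  cat(sprintf("BeatDataset: %d beats x %d samples, %d subjects\n",
              nrow(object@beats),
              if (nrow(object@beats)) ncol(object@beats) else 0L,
              length(unique(object@labels))))
  invisible(NULL)
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf(
    "ModelSpec: conv(%d,%d)-pool(%d)-conv(%d,%d)-pool(%d)-dense(%d)-dropout(%.2f)-softmax(%d), input %d, padding %s\n",
    object@conv1Kernels, object@kernelSize, object@poolSize,
    object@conv2Kernels, object@kernelSize, object@poolSize,
    object@denseUnits, object@dropoutRate, object@nClasses,
    object@inputLen, object@padding))
  invisible(NULL)
})

setMethod("show", "TrainedClassifier", function(object) {
  cat(sprintf("TrainedClassifier: %d classes, %d trainable parameters, %d epochs trained\n",
              object@spec@nClasses, countParameters(object),
              nrow(object@history)))
  invisible(NULL)
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d classes, %d instances\n",
              nrow(object@confusion), sum(object@confusion)))
  cat(sprintf("  accuracy %.4f | macro precision %.4f | macro sensitivity %.4f | macro F1 %.4f\n",
              object@accuracy, object@macroPrecision,
              object@macroSensitivity, object@macroF1))
  invisible(NULL)
})
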
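## Accessor generics and show methods.

#' @rdname PenStream-class
#' @param object,x a PenStream.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname PenStream-class
#' @export
setGeneric("penLabel", function(x) standardGeneric("penLabel"))
#' @rdname PenStream-class
#' @export
setGeneric("penSamples", function(x) standardGeneric("penSamples"))
#' @rdname PenStream-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname PenStream-class
setMethod("subjectId", "PenStream", function(x) x@subjectId)
#' @rdname PenStream-class
setMethod("penLabel", "PenStream", function(x) x@label)
#' @rdname PenStream-class
setMethod("penSamples", "PenStream", function(x) x@samples)
#' @rdname PenStream-class
setMethod("sampleRate", "PenStream", function(x) x@sampleRateHz)

#' @rdname GrayImage-class
#' @param x a GrayImage.
#' @export
setGeneric("grayPixels", function(x) standardGeneric("grayPixels"))
#' @rdname GrayImage-class
setMethod("grayPixels", "GrayImage", function(x) x@pixels)
#' @rdname GrayImage-class
#' @export
setGeneric("imageView", function(x) standardGeneric("imageView"))
#' @rdname GrayImage-class
setMethod("imageView", "GrayImage", function(x) x@view)
#' @rdname GrayImage-class
setMethod("subjectId", "GrayImage", function(x) x@subjectId)

#' @rdname FeatureVector-class
#' @param x a FeatureVector.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname FeatureVector-class
setMethod("featureValues", "FeatureVector", function(x) x@values)
#' @rdname FeatureVector-class
#' @export
setGeneric("featureLayer", function(x) standardGeneric("featureLayer"))
#' @rdname FeatureVector-class
setMethod("featureLayer", "FeatureVector", function(x) x@layer)

#' @rdname KinematicSeries-class
#' @param x a KinematicSeries.
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))
#' @rdname KinematicSeries-class
setMethod("seriesValues", "KinematicSeries", function(x) x@values)

#' @rdname SamplingPlan-class
#' @param x a SamplingPlan.
#' @export
setGeneric("planRepetitions", function(x) standardGeneric("planRepetitions"))
#' @rdname SamplingPlan-class
setMethod("planRepetitions", "SamplingPlan", function(x) x@repetitions)

#' @rdname EvalResult-class
#' @param x an EvalResult.
#' @export
setGeneric("resultSummary", function(x) standardGeneric("resultSummary"))
#' @rdname EvalResult-class
setMethod("resultSummary", "EvalResult", function(x) x@summary)
#' @rdname EvalResult-class
#' @export
setGeneric("resultCounts", function(x) standardGeneric("resultCounts"))
#' @rdname EvalResult-class
setMethod("resultCounts", "EvalResult", function(x) x@perRep)

setMethod("show", "PenStream", function(object) {
  s <- object@samples
  cat(sprintf("PenStream '%s' (%s): %d samples @ %g Hz, %.1f s, %d pen-up sample(s)\n",
              object@subjectId, object@label, nrow(s), object@sampleRateHz,
              if (nrow(s)) diff(range(s$t)) else 0, sum(!s$penDown)))
})

setMethod("show", "GrayImage", function(object) {
  p <- object@pixels
  cat(sprintf("GrayImage '%s' view=%s: %dx%d px, %d ink pixel(s)\n",
              object@subjectId, object@view, nrow(p), ncol(p),
              sum(p < 255L)))
})

setMethod("show", "FeatureVector", function(object) {
  cat(sprintf("FeatureVector %s/%s layer=%s dim=%d\n", object@subjectId,
              object@view, object@layer, length(object@values)))
})

setMethod("show", "SamplingPlan", function(object) {
  r1 <- object@repetitions[[1]]
  cat(sprintf("SamplingPlan: %d repetitions (train %d / test %d per rep), master seed %g\n",
              object@nReps, length(r1$trainIds), length(r1$testIds),
              object@masterSeed))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts (AD positive): tp=%d fn=%d tn=%d fp=%d\n",
              object@tp, object@fn, object@tn, object@fp))
})

setMethod("show", "EvalResult", function(object) {
  s <- object@summary
  cat(sprintf("EvalResult over %d repetition(s):\n", length(object@perRep)))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %5.1f +/- %.1f %%\n", s$metric[i], s$mean[i], s$sd[i]))
})

setMethod("show", "ExpertModel", function(object) {
  cat(sprintf("ExpertModel view=%s layer=%s: C=%g gamma=%g (CV accuracy %.1f%%)\n",
              object@view, object@layer, object@cost, object@gamma,
              100 * object@cvAccuracy))
})
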
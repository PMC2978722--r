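#' @rdname NirsRecording-class
#' @param x,object a NirsRecording (or other object with the accessor)
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname NirsRecording-class
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))

#' @rdname NirsRecording-class
#' @export
setGeneric("oxyHb", function(x) standardGeneric("oxyHb"))

#' @rdname NirsRecording-class
#' @export
setGeneric("deoxyHb", function(x) standardGeneric("deoxyHb"))

#' @rdname NirsRecording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname NirsRecording-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname NirsRecording-class
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname NirsRecording-class
#' @export
setGeneric("t0", function(x) standardGeneric("t0"))

#' @rdname EventSchedule-class
#' @param x,object an EventSchedule
#' @export
setGeneric("onsets", function(x) standardGeneric("onsets"))

#' @rdname EventSchedule-class
#' @export
setGeneric("durations", function(x) standardGeneric("durations"))

#' @rdname EventSchedule-class
#' @export
setGeneric("nBlocks", function(x) standardGeneric("nBlocks"))

#' @rdname EventSchedule-class
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))

setMethod("samplingRate", "NirsRecording", function(x) x@samplingRate)
setMethod("channelIds", "NirsRecording", function(x) x@channelIds)
setMethod("oxyHb", "NirsRecording", function(x) x@oxy)
setMethod("deoxyHb", "NirsRecording", function(x) x@deoxy)
setMethod("nSamples", "NirsRecording", function(x) nrow(x@oxy))
setMethod("nChannels", "NirsRecording", function(x) ncol(x@oxy))
setMethod("t0", "NirsRecording", function(x) x@t0)
setMethod("sampleTimes", "NirsRecording", function(x)
  x@t0 + (seq_len(nrow(x@oxy)) - 1) / x@samplingRate)

setMethod("show", "NirsRecording", function(object) {
  cat(sprintf("NirsRecording: %d samples x %d channels @ %g Hz (%.1f s)\n",
              nSamples(object), nChannels(object), samplingRate(object),
              nSamples(object) / samplingRate(object)))
  cat("  channels:", paste(utils::head(channelIds(object), 6), collapse = ", "),
      if (nChannels(object) > 6) "..." else "", "\n")
})

setMethod("onsets", "EventSchedule", function(x) x@onsets)
setMethod("durations", "EventSchedule", function(x) x@durations)
setMethod("nBlocks", "EventSchedule", function(x) length(x@onsets))
setMethod("totalDuration", "EventSchedule", function(x) x@totalDuration)

setMethod("show", "EventSchedule", function(object) {
  cat(sprintf("EventSchedule: %d blocks over %.1f s\n",
              nBlocks(object), totalDuration(object)))
  if (nBlocks(object))
    cat(sprintf("  first block: onset %.1f s, duration %.1f s\n",
                object@onsets[1], object@durations[1]))
})

setMethod("show", "FeatureSpec", function(object) {
  cat(sprintf("FeatureSpec: %s/%s, history %.2f s, %d channel(s)\n",
              object@signals, object@representation, object@historySec,
              length(object@channels)))
})

#' @rdname FeatureMatrix-class
#' @param x,object a FeatureMatrix
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("validRows", function(x) standardGeneric("validRows"))

setMethod("featureValues", "FeatureMatrix", function(x) x@X)
setMethod("validRows", "FeatureMatrix", function(x) x@valid)
setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d samples x %d features (%d valid rows)\n",
              nrow(object@X), ncol(object@X), sum(object@valid)))
})

setMethod("show", "TrialSplit", function(object) {
  cat(sprintf("TrialSplit: train blocks %s (samples [%d,%d)), test blocks %s (samples [%d,%d))\n",
              paste(range(object@trainBlocks), collapse = "-"),
              object@trainRange[1], object@trainRange[2],
              paste(range(object@testBlocks), collapse = "-"),
              object@testRange[1], object@testRange[2]))
})

#' @rdname TrainedModel-class
#' @param x,object a TrainedModel
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @rdname TrainedModel-class
#' @export
setGeneric("modelBias", function(x) standardGeneric("modelBias"))

setMethod("modelWeights", "TrainedModel", function(x) x@weights)
setMethod("modelBias", "TrainedModel", function(x) x@bias)
setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel: linear SVM, %d features, C = %g, |w| = %.4g\n",
              length(object@weights), object@cost,
              sqrt(sum(object@weights^2))))
})

#' @rdname DelayResult-class
#' @param x,object a DelayResult
#' @export
setGeneric("onsetDelays", function(x) standardGeneric("onsetDelays"))

#' @rdname DelayResult-class
#' @export
setGeneric("offsetDelays", function(x) standardGeneric("offsetDelays"))

#' @rdname DelayResult-class
#' @export
setGeneric("censorCount", function(x) standardGeneric("censorCount"))

#' Summarize a DelayResult
#'
#' Mean and standard error (n-1 denominator across trials) of onset and
#' offset delays over uncensored trials.
#'
#' @rdname DelayResult-class
#' @export
setGeneric("delaySummary", function(x) standardGeneric("delaySummary"))

setMethod("onsetDelays", "DelayResult", function(x) x@onsetDelays)
setMethod("offsetDelays", "DelayResult", function(x) x@offsetDelays)
setMethod("censorCount", "DelayResult", function(x)
  sum(is.na(x@onsetDelays)) + sum(is.na(x@offsetDelays)))

.meanSe <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(c(mean = NA_real_, se = NA_real_))
  se <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  c(mean = mean(v), se = se)
}

setMethod("delaySummary", "DelayResult", function(x) {
  on <- .meanSe(x@onsetDelays); off <- .meanSe(x@offsetDelays)
  data.frame(
    meanOnset = on[["mean"]], seOnset = on[["se"]],
    meanOffset = off[["mean"]], seOffset = off[["se"]],
    nTrials = length(x@onsetDelays),
    onsetCensored = sum(is.na(x@onsetDelays)),
    offsetCensored = sum(is.na(x@offsetDelays))
  )
})

setMethod("show", "DelayResult", function(object) {
  s <- delaySummary(object)
  cat(sprintf("DelayResult (%d trials): onset %.2f s (se %.2f, %d censored), offset %.2f s (se %.2f, %d censored)\n",
              s$nTrials, s$meanOnset, s$seOnset, s$onsetCensored,
              s$meanOffset, s$seOffset, s$offsetCensored))
})

#' @rdname SweepResult-class
#' @param x,object a SweepResult
#' @export
setGeneric("sweepMetrics", function(x) standardGeneric("sweepMetrics"))

#' @rdname SweepResult-class
#' @export
setGeneric("sweepOptimum", function(x) standardGeneric("sweepOptimum"))

setMethod("sweepMetrics", "SweepResult", function(x) x@metrics)
setMethod("sweepOptimum", "SweepResult", function(x) x@optimum)
setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult over %s (%d values); optimum: %s\n",
              object@axisName, nrow(object@metrics),
              format(object@optimum)))
  print(object@metrics, row.names = FALSE)
})
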
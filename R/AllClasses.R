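#' @import methods
NULL

#' NirsRecording: multi-channel oxy-/deoxy-hemoglobin time series
#'
#' Container for a continuous fNIRS recording: one matrix per chromophore
#' (samples in rows, channels in columns, concentration change in arbitrary
#' units such as mM*mm), the sampling rate, ordered channel identifiers and
#' the time of the first sample. Sample \code{k} (1-based) is at time
#' \code{t0(x) + (k - 1) / samplingRate(x)} seconds.
#'
#' @slot samplingRate sampling rate in Hz (positive scalar)
#' @slot channelIds character vector of channel identifiers
#' @slot oxy numeric matrix, n_samples x n_channels, oxy-Hb signal
#' @slot deoxy numeric matrix, same shape, deoxy-Hb signal
#' @slot t0 time of the first sample in seconds (default 0)
#'
#' @aliases NirsRecording-class
#' @exportClass NirsRecording
setClass("NirsRecording",
  representation(
    samplingRate = "numeric",
    channelIds = "character",
    oxy = "matrix",
    deoxy = "matrix",
    t0 = "numeric"
  ),
  prototype(t0 = 0)
)

setValidity("NirsRecording", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a positive finite scalar")
  if (!identical(dim(object@oxy), dim(object@deoxy)))
    msg <- c(msg, "oxy and deoxy matrices must have identical shape")
  if (ncol(object@oxy) != length(object@channelIds))
    msg <- c(msg, "number of columns must equal length(channelIds)")
  if (anyDuplicated(object@channelIds))
    msg <- c(msg, "channelIds must be unique")
  if (any(!is.finite(object@oxy)) || any(!is.finite(object@deoxy)))
    msg <- c(msg, "signal matrices contain NaN/Inf or NA values")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a finite scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a NirsRecording
#'
#' @param oxy,deoxy numeric matrices (n_samples x n_channels)
#' @param samplingRate sampling rate in Hz
#' @param channelIds channel identifiers; defaults to the column names of
#'   \code{oxy}, or \code{"ch1"..."chK"}
#' @param t0 time of first sample in seconds
#' @return a \linkS4class{NirsRecording}
#' @examples
#' rec <- NirsRecording(matrix(rnorm(20), 10), matrix(rnorm(20), 10), 10)
#' nSamples(rec)
#' @export
NirsRecording <- function(oxy, deoxy, samplingRate, channelIds = NULL, t0 = 0) {
  oxy <- as.matrix(oxy)
  deoxy <- as.matrix(deoxy)
  if (is.null(channelIds)) {
    channelIds <- colnames(oxy)
    if (is.null(channelIds)) channelIds <- paste0("ch", seq_len(ncol(oxy)))
  }
  colnames(oxy) <- colnames(deoxy) <- channelIds
  new("NirsRecording", samplingRate = as.numeric(samplingRate),
      channelIds = as.character(channelIds),
      oxy = oxy, deoxy = deoxy, t0 = as.numeric(t0))
}

#' EventSchedule: block-design task timing
#'
#' Ordered, non-overlapping task blocks given by onset and duration in
#' seconds, together with the total duration of the recording they annotate.
#' Every block interval is half-open: \code{[onset, onset + duration)}.
#'
#' @slot onsets block onsets in seconds, sorted increasing
#' @slot durations block durations in seconds, all positive
#' @slot totalDuration recording duration in seconds
#'
#' @aliases EventSchedule-class
#' @exportClass EventSchedule
setClass("EventSchedule",
  representation(
    onsets = "numeric",
    durations = "numeric",
    totalDuration = "numeric"
  )
)

setValidity("EventSchedule", function(object) {
  o <- object@onsets; d <- object@durations
  msg <- character()
  if (length(o) != length(d))
    msg <- c(msg, "onsets and durations must have equal length")
  if (any(d <= 0))
    msg <- c(msg, sprintf("non-positive durations at blocks: %s",
                          paste(which(d <= 0), collapse = ", ")))
  if (length(o) > 1 && is.unsorted(o, strictly = FALSE))
    msg <- c(msg, "blocks must be sorted by onset")
  if (length(o) > 1) {
    bad <- which(o[-1] < (o + d)[-length(o)])
    if (length(bad))
      msg <- c(msg, sprintf("overlapping blocks at positions: %s",
                            paste(bad, collapse = ", ")))
  }
  if (length(o) && (any(o < 0) || any(o + d > object@totalDuration + 1e-9)))
    msg <- c(msg, "every block must lie within [0, totalDuration]")
  if (length(msg)) msg else TRUE
})

#' Construct an EventSchedule
#'
#' Blocks may be supplied in any order; they are sorted by onset before
#' validation (overlap after sorting is an error).
#'
#' @param onsets block onsets in seconds
#' @param durations block durations in seconds (recycled if scalar)
#' @param totalDuration recording duration in seconds; defaults to the end of
#'   the last block
#' @return an \linkS4class{EventSchedule}
#' @examples
#' EventSchedule(c(20, 50), 10, totalDuration = 90)
#' @export
EventSchedule <- function(onsets, durations, totalDuration = NULL) {
  onsets <- as.numeric(onsets)
  durations <- rep_len(as.numeric(durations), length(onsets))
  ord <- order(onsets)
  onsets <- onsets[ord]; durations <- durations[ord]
  if (is.null(totalDuration))
    totalDuration <- if (length(onsets)) max(onsets + durations) else 0
  new("EventSchedule", onsets = onsets, durations = durations,
      totalDuration = as.numeric(totalDuration))
}

#' FeatureSpec: declarative description of a decoding feature space
#'
#' @slot historySec length of the history window in seconds (>= 0); the
#'   number of history samples is \code{y = round(historySec * fs)}
#' @slot representation one of \code{"amplitude"}, \code{"gradient1"},
#'   \code{"gradient2"}
#' @slot signals one of \code{"oxy"}, \code{"deoxy"}, \code{"both"},
#'   \code{"total"}, \code{"cbsi"}
#' @slot channels ordered character vector of channel ids to include
#'
#' @aliases FeatureSpec-class
#' @exportClass FeatureSpec
setClass("FeatureSpec",
  representation(
    historySec = "numeric",
    representation = "character",
    signals = "character",
    channels = "character"
  )
)

.REPRESENTATIONS <- c("amplitude", "gradient1", "gradient2")
.SIGNALS <- c("oxy", "deoxy", "both", "total", "cbsi")

setValidity("FeatureSpec", function(object) {
  msg <- character()
  if (length(object@historySec) != 1L || object@historySec < 0)
    msg <- c(msg, "historySec must be a single value >= 0")
  if (!object@representation %in% .REPRESENTATIONS)
    msg <- c(msg, sprintf("representation must be one of: %s",
                          paste(.REPRESENTATIONS, collapse = ", ")))
  if (!object@signals %in% .SIGNALS)
    msg <- c(msg, sprintf("signals must be one of: %s",
                          paste(.SIGNALS, collapse = ", ")))
  if (length(object@channels) == 0L)
    msg <- c(msg, "channels must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureSpec
#'
#' @param channels ordered channel ids
#' @param historySec history window length in seconds
#' @param representation "amplitude", "gradient1" or "gradient2"
#' @param signals chromophore combination: "oxy", "deoxy", "both", "total"
#'   or "cbsi"
#' @return a \linkS4class{FeatureSpec}
#' @examples
#' FeatureSpec("ch1", historySec = 2)
#' @export
FeatureSpec <- function(channels, historySec = 1, representation = "amplitude",
                        signals = "oxy") {
  new("FeatureSpec", historySec = as.numeric(historySec),
      representation = match.arg(representation, .REPRESENTATIONS),
      signals = match.arg(signals, .SIGNALS),
      channels = as.character(channels))
}

#' FeatureMatrix: realized per-timepoint design matrix
#'
#' One row per recording sample; rows lacking a complete history window are
#' flagged invalid and excluded from training and accuracy computation.
#' Column names encode \code{channel.signal.lag<k>}.
#'
#' @slot X numeric matrix, n_samples x m
#' @slot valid logical vector of length n_samples
#' @slot spec the \linkS4class{FeatureSpec} that produced the matrix
#'
#' @aliases FeatureMatrix-class
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(X = "matrix", valid = "logical", spec = "FeatureSpec")
)

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (length(object@valid) != nrow(object@X))
    msg <- c(msg, "valid mask length must equal nrow(X)")
  if (is.null(colnames(object@X)))
    msg <- c(msg, "X must carry column names")
  if (length(msg)) msg else TRUE
})

#' TrialSplit: first-half-train / second-half-test assignment
#'
#' The first ceiling(n/2) blocks, together with the rest period that follows
#' each of them up to the next block's onset, form the training range; the
#' remaining blocks form the test range. Ranges are half-open sample-index
#' intervals \code{[start, end)} (1-based), disjoint, and jointly cover the
#' recording.
#'
#' @slot trainBlocks integer indices of training blocks
#' @slot testBlocks integer indices of test blocks
#' @slot trainRange integer c(start, end), half-open
#' @slot testRange integer c(start, end), half-open
#'
#' @aliases TrialSplit-class
#' @exportClass TrialSplit
setClass("TrialSplit",
  representation(
    trainBlocks = "integer",
    testBlocks = "integer",
    trainRange = "integer",
    testRange = "integer"
  )
)

#' TrainedModel: linear per-timepoint decision rule
#'
#' Prediction is \code{sign(w . x + b)} with a decision value of exactly 0
#' mapped to -1 (rest).
#'
#' @slot weights numeric weight vector, one per feature column
#' @slot bias intercept
#' @slot cost soft-margin penalty C used in training
#' @slot spec snapshot of the \linkS4class{FeatureSpec} used
#' @slot columnNames feature column names the weights refer to
#'
#' @aliases TrainedModel-class
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(
    weights = "numeric",
    bias = "numeric",
    cost = "numeric",
    spec = "FeatureSpec",
    columnNames = "character"
  )
)

setValidity("TrainedModel", function(object) {
  msg <- character()
  if (length(object@weights) != length(object@columnNames))
    msg <- c(msg, "weights length must match columnNames length")
  if (length(object@cost) != 1L || object@cost <= 0)
    msg <- c(msg, "cost must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' DelayResult: per-trial onset and offset detection delays
#'
#' A trial whose search window contains no qualifying sample is censored and
#' recorded as NA; summary means and standard errors (n-1 denominator, across
#' trials) are computed over uncensored trials only.
#'
#' @slot onsetDelays per-trial onset delays in seconds (NA = censored)
#' @slot offsetDelays per-trial offset delays in seconds (NA = censored)
#'
#' @aliases DelayResult-class
#' @exportClass DelayResult
setClass("DelayResult",
  representation(onsetDelays = "numeric", offsetDelays = "numeric")
)

setValidity("DelayResult", function(object) {
  if (length(object@onsetDelays) != length(object@offsetDelays))
    return("onset and offset delay vectors must have equal length (one per trial)")
  if (any(object@onsetDelays < 0, na.rm = TRUE) ||
      any(object@offsetDelays < 0, na.rm = TRUE))
    return("delays must be non-negative")
  TRUE
})

#' SweepResult: metrics along one experimental axis
#'
#' @slot axisName name of the swept axis (e.g. "historySec", "signals",
#'   "nChannels")
#' @slot metrics data.frame with one row per axis value: columns
#'   \code{value}, \code{accuracy}, \code{onsetDelay}, \code{offsetDelay},
#'   \code{onsetCensored}, \code{offsetCensored}
#' @slot optimum the axis value maximizing accuracy (first on ties)
#'
#' @aliases SweepResult-class
#' @exportClass SweepResult
setClass("SweepResult",
  representation(axisName = "character", metrics = "data.frame",
                 optimum = "ANY")
)

setValidity("SweepResult", function(object) {
  need <- c("value", "accuracy", "onsetDelay", "offsetDelay")
  if (!all(need %in% names(object@metrics)))
    return(sprintf("metrics must contain columns: %s",
                   paste(need, collapse = ", ")))
  TRUE
})
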
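#' Per-timepoint classification accuracy
#'
#' Fraction of valid samples whose predicted label equals the behavioral
#' label.
#'
#' @param pred,truth +1/-1 label vectors of equal length
#' @param valid logical mask of samples to score (default: all)
#' @return accuracy in [0, 1]
#' @export
classificationAccuracy <- function(pred, truth, valid = NULL) {
  if (length(pred) != length(truth)) stop("label length mismatch")
  if (is.null(valid)) valid <- rep(TRUE, length(pred))
  if (!any(valid)) stop("no valid samples to score")
  mean(pred[valid] == truth[valid])
}

#' Onset and offset detection delays per trial
#'
#' For each block: the onset delay is the time from the block onset to the
#' first sample at or after it classified +1 (searching up to the next
#' block's onset, or the end of the predictions); the offset delay is the
#' time from the block offset to the first sample at or after it classified
#' -1 (same search bound). A trial with no qualifying sample in its search
#' window is censored (NA). Detections before the event never count:
#' delays are non-negative by construction.
#'
#' @param pred +1/-1 predicted labels covering all blocks of interest
#' @param events the blocks to evaluate (normally the test half)
#' @param fs sampling rate in Hz
#' @param t0 time of the first prediction sample
#' @return a \linkS4class{DelayResult}
#' @export
onsetOffsetDelays <- function(pred, events, fs, t0 = 0) {
  nb <- nBlocks(events)
  if (nb < 1L) stop("no blocks to evaluate")
  tt <- t0 + (seq_along(pred) - 1) / fs
  endTime <- t0 + length(pred) / fs
  if (any(onsets(events) + durations(events) > endTime + 1e-9))
    stop("a block lies outside the prediction range")
  onsetD <- offsetD <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    o <- onsets(events)[b]
    f <- o + durations(events)[b]
    nxt <- if (b < nb) onsets(events)[b + 1L] else endTime
    i <- which(tt >= o - 1e-9 & tt < nxt & pred == 1L)[1]
    if (!is.na(i)) onsetD[b] <- tt[i] - o
    j <- which(tt >= f - 1e-9 & tt < nxt & pred == -1L)[1]
    if (!is.na(j)) offsetD[b] <- tt[j] - f
  }
  new("DelayResult", onsetDelays = pmax(onsetD, 0),
      offsetDelays = pmax(offsetD, 0))
}
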
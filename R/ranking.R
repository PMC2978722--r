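#' Contrast-to-noise ratio of one channel
#'
#' CNR = (mean of task-window samples - mean of rest-window samples) divided
#' by the pooled standard deviation
#' \code{sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))}. Task and rest
#' samples are pooled across all supplied blocks; windows are half-open
#' \code{[start, end)} in seconds relative to each block's onset. The default
#' task window 6-12 s after onset accounts for the hemodynamic delay; the
#' default rest window is the 5 s before onset.
#'
#' @param x numeric series (one channel, normally EMA-filtered)
#' @param events an \linkS4class{EventSchedule} (normally training blocks
#'   only)
#' @param fs sampling rate in Hz
#' @param taskWindow,restWindow (start, end) in seconds relative to onset
#' @param t0 time of the first sample of \code{x}
#' @param pooling "samples" (default) pools raw samples across blocks;
#'   "blockmean" uses per-block window means as the observations
#' @return the CNR, a single number
#' @export
cnr <- function(x, events, fs, taskWindow = c(6, 12), restWindow = c(-5, 0),
                t0 = 0, pooling = c("samples", "blockmean")) {
  pooling <- match.arg(pooling)
  stopifnot(taskWindow[1] < taskWindow[2], restWindow[1] < restWindow[2])
  if (nBlocks(events) < 1L) stop("at least one block required")
  tt <- t0 + (seq_along(x) - 1) / fs
  grab <- function(win) {
    lapply(onsets(events), function(o)
      x[tt >= o + win[1] & tt < o + win[2]])
  }
  taskL <- grab(taskWindow); restL <- grab(restWindow)
  if (pooling == "samples") {
    task <- unlist(taskL); rest <- unlist(restL)
  } else {
    task <- vapply(taskL, mean, 0); rest <- vapply(restL, mean, 0)
  }
  if (length(task) < 2L || length(rest) < 2L)
    stop("fewer than 2 samples in the task or rest window after discretization")
  n1 <- length(task); n2 <- length(rest)
  sp <- sqrt(((n1 - 1) * stats::var(task) + (n2 - 1) * stats::var(rest)) /
               (n1 + n2 - 2))
  (mean(task) - mean(rest)) / sp
}

#' Rank channels by decreasing contrast-to-noise ratio
#'
#' Computes the CNR of every channel on the supplied blocks (pass the
#' training blocks only, so channel selection never sees test data) and
#' orders channels by decreasing CNR; ties keep the recording's channel
#' order.
#'
#' @param rec a filtered \linkS4class{NirsRecording}
#' @param events blocks to compute CNR on (training blocks)
#' @param taskWindow,restWindow,pooling see \code{\link{cnr}}
#' @param chromophore "oxy" (default) or "deoxy"
#' @return data.frame with columns \code{channel}, \code{cnr}, \code{rank},
#'   ordered by rank
#' @export
rankChannels <- function(rec, events, taskWindow = c(6, 12),
                         restWindow = c(-5, 0),
                         chromophore = c("oxy", "deoxy"),
                         pooling = c("samples", "blockmean")) {
  chromophore <- match.arg(chromophore)
  pooling <- match.arg(pooling)
  m <- if (chromophore == "oxy") oxyHb(rec) else deoxyHb(rec)
  vals <- vapply(seq_len(ncol(m)), function(c)
    cnr(m[, c], events, samplingRate(rec), taskWindow, restWindow,
        t0 = t0(rec), pooling = pooling), 0)
  ord <- order(-vals, seq_along(vals))
  data.frame(channel = channelIds(rec)[ord], cnr = vals[ord],
             rank = seq_along(ord))
}
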
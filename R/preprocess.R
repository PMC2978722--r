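#' Causal exponential moving average
#'
#' Recursive smoother \code{M(1) = x(1); M(t) = lambda * x(t) +
#' (1 - lambda) * M(t-1)}. The span \code{alpha} is given in samples;
#' \code{lambda} follows the chosen convention: \code{"standard"} uses
#' \code{lambda = 2 / (alpha + 1)} (so alpha = 20 at 10 Hz corresponds to a
#' 2 s window in the conventional EMA-span sense), \code{"reciprocal"} uses
#' \code{lambda = 1 / alpha}. Strictly causal: the output at t depends only
#' on x(1..t).
#'
#' @param x numeric series
#' @param alpha span in samples (> 1)
#' @param lambdaRule "standard" or "reciprocal"
#' @return the smoothed series, same length as \code{x}
#' @export
emaMovingAverage <- function(x, alpha, lambdaRule = c("standard", "reciprocal")) {
  lambdaRule <- match.arg(lambdaRule)
  if (alpha <= 1) stop("alpha must exceed 1")
  if (length(x) < 1L) stop("series must have at least one sample")
  lambda <- if (lambdaRule == "standard") 2 / (alpha + 1) else 1 / alpha
  m <- numeric(length(x))
  acc <- x[1]
  m[1] <- acc
  for (t in seq_along(x)[-1]) {
    # increment form of M(t) = lambda x(t) + (1-lambda) M(t-1): a constant
    # input is an exact floating-point fixed point, so S - L of a constant
    # series is exactly zero
    acc <- acc + lambda * (x[t] - acc)
    m[t] <- acc
  }
  m
}

#' Window duration of an EMA span
#'
#' Reports the effective moving-average window of a span-\code{alpha} EMA in
#' seconds at sampling rate \code{fs}: \code{alpha / fs} (e.g. a span of 20
#' samples at 10 Hz is a 2 s window).
#'
#' @param alpha span in samples
#' @param fs sampling rate in Hz
#' @return window duration in seconds
#' @export
emaWindowSec <- function(alpha, fs) {
  stopifnot(alpha > 1, fs > 0)
  alpha / fs
}

#' Online band-pass detrending by EMA difference
#'
#' Computes long- and short-span exponential moving averages of the signal
#' and returns their difference \code{g = S - L}. The long average tracks
#' slow drift, the short average suppresses high-frequency instrument noise,
#' so the difference acts as a causal, O(1)-per-sample band-pass filter. Both
#' averages are initialized to \code{x(1)}, hence \code{g(1) = 0} exactly and
#' the filter is invariant to adding a constant to the input.
#'
#' @param x numeric series
#' @param alphaLong long-term span in samples (default 100)
#' @param alphaShort short-term span in samples (default 20)
#' @param lambdaRule smoothing-factor convention, see
#'   \code{\link{emaMovingAverage}}
#' @return the filtered series \code{g}
#' @examples
#' emaFilter(rep(3, 10))  # identically zero
#' @export
emaFilter <- function(x, alphaLong = 100, alphaShort = 20,
                      lambdaRule = c("standard", "reciprocal")) {
  lambdaRule <- match.arg(lambdaRule)
  if (alphaShort >= alphaLong)
    stop("alphaShort must be smaller than alphaLong")
  emaMovingAverage(x, alphaShort, lambdaRule) -
    emaMovingAverage(x, alphaLong, lambdaRule)
}

#' Filter every channel and chromophore of a recording
#'
#' Applies \code{\link{emaFilter}} independently to each column of the oxy
#' and deoxy matrices. All signals are filtered this way before feature
#' construction and CNR computation.
#'
#' @param rec a \linkS4class{NirsRecording}
#' @param cfg a \code{\link{pipelineConfig}} supplying the EMA parameters
#' @return a filtered \linkS4class{NirsRecording}
#' @export
filterRecording <- function(rec, cfg = pipelineConfig()) {
  f <- function(m) apply(m, 2L, emaFilter, alphaLong = cfg$emaAlphaLong,
                         alphaShort = cfg$emaAlphaShort,
                         lambdaRule = cfg$lambdaRule)
  .log("EMA filter: alphaLong=%g alphaShort=%g rule=%s",
       cfg$emaAlphaLong, cfg$emaAlphaShort, cfg$lambdaRule)
  NirsRecording(f(oxyHb(rec)), f(deoxyHb(rec)), samplingRate(rec),
                channelIds(rec), t0(rec))
}
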
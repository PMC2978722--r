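#' Finite-difference signal gradient
#'
#' First order: \code{d(t) = x(t) - x(t-1)}. Second order:
#' \code{d2(t) = x(t) - 2 x(t-1) + x(t-2)}, the gradient of the first-order
#' gradient. The first \code{order} outputs have no complete history and are
#' returned as NA.
#'
#' @param x numeric series
#' @param order 1 or 2
#' @return numeric series of the same length, leading \code{order} entries NA
#' @examples
#' signalGradient(3 * (1:5), 1)  # NA 3 3 3 3
#' @export
signalGradient <- function(x, order = 1L) {
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  if (length(x) < order + 1L) stop("series too short for gradient of order ", order)
  d <- if (order == 1L) c(NA_real_, diff(x))
  else c(NA_real_, NA_real_, diff(diff(x)))
  d
}

#' Correlation-based signal improvement (CBSI) corrected oxy-Hb
#'
#' Exploits the typical anti-correlation of oxy- and deoxy-Hb: assuming the
#' true signals satisfy deoxy = -oxy/alpha plus common-mode noise, with
#' \code{alpha = sd(oxy) / sd(deoxy)} the corrected signal
#' \code{(oxy - alpha * deoxy) / 2} cancels noise that moves both
#' chromophores in the same direction (e.g. motion).
#'
#' @param oxy,deoxy numeric series of equal length (>= 2)
#' @param alpha optional precomputed scale factor; supplied by the pipeline
#'   when alpha must come from the training portion only
#' @return the corrected oxy series
#' @examples
#' x <- rnorm(50); all.equal(cbsiCorrect(x, -x), x)
#' @export
cbsiCorrect <- function(oxy, deoxy, alpha = NULL) {
  if (length(oxy) != length(deoxy)) stop("oxy and deoxy length mismatch")
  if (length(oxy) < 2L) stop("series too short")
  if (is.null(alpha)) alpha <- cbsiAlpha(oxy, deoxy)
  (oxy - alpha * deoxy) / 2
}

#' @rdname cbsiCorrect
#' @export
cbsiAlpha <- function(oxy, deoxy) {
  sdd <- stats::sd(deoxy)
  if (!is.finite(sdd) || sdd == 0)
    stop("CBSI scale undefined: deoxy series has zero variance")
  stats::sd(oxy) / sdd
}

#' Total hemoglobin
#'
#' Elementwise sum of the oxy- and deoxy-Hb series.
#'
#' @param oxy,deoxy numeric series of equal length
#' @return their sum
#' @export
totalHb <- function(oxy, deoxy) {
  if (length(oxy) != length(deoxy)) stop("oxy and deoxy length mismatch")
  oxy + deoxy
}

# The per-channel base series for a chromophore combination. CBSI alpha is
# estimated on trainSamples only (all samples when NULL) to avoid test-set
# leakage.
.channelSeries <- function(rec, channel, signals, trainSamples = NULL) {
  o <- oxyHb(rec)[, channel]
  d <- deoxyHb(rec)[, channel]
  switch(signals,
    oxy = list(oxy = o),
    deoxy = list(deoxy = d),
    both = list(oxy = o, deoxy = d),
    total = list(total = totalHb(o, d)),
    cbsi = {
      idx <- if (is.null(trainSamples)) seq_along(o) else trainSamples
      list(cbsi = cbsiCorrect(o, d, alpha = cbsiAlpha(o[idx], d[idx])))
    })
}

# Lagged copies of x: columns lag 0..y. Rows without full history are NA.
.lagMatrix <- function(x, y) {
  n <- length(x)
  m <- matrix(NA_real_, n, y + 1L)
  for (k in 0:y) m[(k + 1L):n, k + 1L] <- x[seq_len(n - k)]
  m
}

#' Assemble a per-timepoint feature matrix
#'
#' For each requested channel and each series of the chromophore combination,
#' the columns are the current sample plus \code{y = round(historySec * fs)}
#' history samples. For the gradient representations the current amplitude is
#' kept as one dimension and the remaining \code{y} columns are the first- or
#' second-order gradients at lags 0..y-1, so the dimension matches the
#' amplitude space at the same history length. Rows lacking a complete
#' history window are flagged invalid. The column count is
#' \code{(y + 1) * nSeriesPerChannel * nChannels}.
#'
#' @param rec a filtered \linkS4class{NirsRecording}
#' @param spec a \linkS4class{FeatureSpec}
#' @param trainSamples optional integer sample indices of the training range;
#'   used only to estimate the CBSI scale without touching test samples
#' @return a \linkS4class{FeatureMatrix}
#' @examples
#' sim <- generateRecording(simulationSpec(nChannels = 2, nTrials = 2))
#' fm <- assembleFeatures(sim$recording, FeatureSpec("ch01", historySec = 2))
#' ncol(featureValues(fm))  # 21 at 10 Hz
#' @export
assembleFeatures <- function(rec, spec, trainSamples = NULL) {
  stopifnot(is(spec, "FeatureSpec"))
  missing <- setdiff(spec@channels, channelIds(rec))
  if (length(missing))
    stop("unknown channels: ", paste(missing, collapse = ", "))
  fs <- samplingRate(rec)
  y <- as.integer(round(spec@historySec * fs))
  n <- nSamples(rec)
  if (y >= n) stop("history window (", y, " samples) must be shorter than the recording")

  cols <- list()
  for (ch in spec@channels) {
    series <- .channelSeries(rec, ch, spec@signals, trainSamples)
    for (nm in names(series)) {
      x <- series[[nm]]
      block <- if (spec@representation == "amplitude" || y == 0L) {
        b <- .lagMatrix(x, y)
        colnames(b) <- sprintf("%s.%s.amp%d", ch, nm, 0:y)
        b
      } else {
        ord <- if (spec@representation == "gradient1") 1L else 2L
        g <- signalGradient(x, ord)
        b <- cbind(x, .lagMatrix(g, y - 1L))
        colnames(b) <- c(sprintf("%s.%s.amp0", ch, nm),
                         sprintf("%s.%s.grad%d.lag%d", ch, nm, ord, 0:(y - 1L)))
        b
      }
      cols[[length(cols) + 1L]] <- block
    }
  }
  X <- do.call(cbind, cols)
  valid <- !apply(X, 1L, anyNA)
  X[!valid, ] <- 0
  new("FeatureMatrix", X = X, valid = valid, spec = spec)
}
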
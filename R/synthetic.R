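#' Canonical double-gamma hemodynamic response
#'
#' Difference of two gamma densities (the SPM-style canonical shape),
#' normalized to unit peak amplitude. With rate 1 and shapes
#' \code{peakDelay + 1} and \code{undershootDelay + 1}, the positive lobe's
#' mode sits at \code{peakDelay} seconds, the conventional ~6 s peak of the
#' cortical blood-flow response.
#'
#' @param t time grid in seconds (non-negative, increasing)
#' @param peakDelay time-to-peak of the positive lobe, seconds (default 6)
#' @param undershootDelay time-to-trough of the undershoot, seconds
#'   (default 16)
#' @param ratio undershoot amplitude relative to the peak lobe (default 1/6)
#' @return numeric vector, the response sampled on \code{t}; zero at t = 0
#' @examples
#' h <- hemodynamicResponse(seq(0, 30, by = 0.1))
#' seq(0, 30, by = 0.1)[which.max(h)]  # ~6 s
#' @export
hemodynamicResponse <- function(t, peakDelay = 6, undershootDelay = 16,
                                ratio = 1 / 6) {
  if (peakDelay <= 0 || undershootDelay <= 0 || ratio < 0)
    stop("hemodynamic response shape parameters must be positive")
  if (any(t < 0)) stop("time grid must be non-negative")
  raw <- function(tt) stats::dgamma(tt, shape = peakDelay + 1, rate = 1) -
    ratio * stats::dgamma(tt, shape = undershootDelay + 1, rate = 1)
  peak <- max(raw(seq(0, peakDelay + 4, by = 1e-3)))
  raw(t) / peak
}

#' Specification of a synthetic block-design fNIRS recording
#'
#' Defaults mirror a standard motor-cortex finger-tapping protocol: 10 Hz
#' sampling, 10 s task blocks alternating with 20 s rest, a full rest lead-in
#' before the first block, a ~6 s-peaking hemodynamic response, oxy-Hb
#' increase with a proportional deoxy-Hb decrease, slow sinusoidal-plus-linear
#' drift and white instrument noise. Per-channel oxy activation gains decay
#' geometrically so the channels have a well-defined true responsiveness
#' order. Amplitudes are in arbitrary concentration-change units scaled so a
#' single task block evokes a unit-peak response on a gain-1 channel.
#'
#' @param nChannels number of measurement channels
#' @param nTrials number of task blocks (>= 2; the decoder splits them in half)
#' @param taskSec task block duration, seconds
#' @param restSec rest period duration, seconds
#' @param fs sampling rate, Hz
#' @param hrfPeak,hrfUndershoot,hrfRatio double-gamma response parameters
#'   (see \code{\link{hemodynamicResponse}})
#' @param channelAmplitudes per-channel oxy activation gains (>= 0; 0 marks
#'   a null channel); default geometric decay \code{0.85^(c-1)}
#' @param deoxyRatio deoxy amplitude relative to oxy (negative; default -0.35)
#' @param deoxyLagSec lag of the deoxy response behind oxy, seconds (>= 0)
#' @param driftSinusoids,driftMaxFreq,driftAmplitude slow-drift model: number
#'   of random-phase sinusoids, their maximum frequency in Hz, and the
#'   amplitude scale of sinusoids and linear trend
#' @param noiseSd standard deviation of i.i.d. Gaussian instrument noise
#' @param seed integer seed making the recording fully reproducible
#' @return a list with class \code{"SimulationSpec"}
#' @export
simulationSpec <- function(nChannels = 48, nTrials = 10, taskSec = 10,
                           restSec = 20, fs = 10,
                           hrfPeak = 6, hrfUndershoot = 16, hrfRatio = 0.45,
                           channelAmplitudes = 0.85^(seq_len(nChannels) - 1),
                           deoxyRatio = -0.35, deoxyLagSec = 0,
                           driftSinusoids = 3, driftMaxFreq = 0.01,
                           driftAmplitude = 0.2, noiseSd = 0.25,
                           seed = 1L) {
  stopifnot(fs > 0, taskSec > 0, restSec > 0, nTrials >= 2,
            length(channelAmplitudes) == nChannels,
            all(channelAmplitudes >= 0), any(channelAmplitudes > 0),
            deoxyLagSec >= 0, noiseSd >= 0, driftAmplitude >= 0)
  structure(list(
    nChannels = as.integer(nChannels), nTrials = as.integer(nTrials),
    taskSec = taskSec, restSec = restSec, fs = fs,
    hrfPeak = hrfPeak, hrfUndershoot = hrfUndershoot, hrfRatio = hrfRatio,
    channelAmplitudes = channelAmplitudes, deoxyRatio = deoxyRatio,
    deoxyLagSec = deoxyLagSec, driftSinusoids = as.integer(driftSinusoids),
    driftMaxFreq = driftMaxFreq, driftAmplitude = driftAmplitude,
    noiseSd = noiseSd, seed = as.integer(seed)
  ), class = "SimulationSpec")
}

# Boxcar convolved with the sampled response kernel, normalized so an
# isolated task block reaches peak 1 on a gain-1 channel.
.blockResponse <- function(u, spec, lagSamples = 0L) {
  fs <- spec$fs
  kGrid <- seq(0, 32, by = 1 / fs)
  kern <- hemodynamicResponse(kGrid, spec$hrfPeak, spec$hrfUndershoot,
                              spec$hrfRatio) / fs
  single <- rep(0, length(u))
  single[seq_len(round(spec$taskSec * fs))] <- 1
  norm <- max(.causalConv(single, kern))
  if (lagSamples > 0L) u <- c(rep(0, lagSamples), u)[seq_along(u)]
  .causalConv(u, kern) / norm
}

.causalConv <- function(u, kern) {
  out <- stats::convolve(u, rev(kern), type = "open")
  out[seq_along(u)]
}

.driftTrace <- function(n, fs, spec) {
  tt <- (seq_len(n) - 1) / fs
  d <- numeric(n)
  if (spec$driftAmplitude > 0) {
    for (j in seq_len(spec$driftSinusoids)) {
      f <- stats::runif(1, 0.001, spec$driftMaxFreq)
      a <- stats::runif(1, 0, spec$driftAmplitude)
      ph <- stats::runif(1, 0, 2 * pi)
      d <- d + a * sin(2 * pi * f * tt + ph)
    }
    slope <- stats::runif(1, -spec$driftAmplitude, spec$driftAmplitude)
    d <- d + slope * tt / max(tt[n], 1)
  }
  d
}

#' Generate a synthetic block-design recording with known ground truth
#'
#' The oxy-Hb signal of channel c is
#' \code{amplitude_c * (boxcar convolved with the hemodynamic response) +
#' drift + noise}; the deoxy-Hb signal is the same response scaled by the
#' (negative) \code{deoxyRatio}, optionally lagged, with its own independent
#' drift and noise. The schedule starts with one full rest period before the
#' first block so a pre-block rest window always exists.
#'
#' @param spec a \code{\link{simulationSpec}}
#' @return a list with elements \code{recording}
#'   (\linkS4class{NirsRecording}), \code{events}
#'   (\linkS4class{EventSchedule}) and \code{groundTruth} (named per-channel
#'   oxy amplitudes)
#' @examples
#' sim <- generateRecording(simulationSpec(nChannels = 4, nTrials = 2))
#' sim$recording
#' @export
generateRecording <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  fs <- spec$fs
  cycle <- spec$taskSec + spec$restSec
  total <- spec$restSec + spec$nTrials * cycle
  n <- round(total * fs)
  blockOnsets <- spec$restSec + (seq_len(spec$nTrials) - 1) * cycle
  events <- EventSchedule(blockOnsets, spec$taskSec, totalDuration = total)

  u <- as.numeric(labelTimepoints(events, n, fs) == 1)
  respOxy <- .blockResponse(u, spec)
  respDeoxy <- .blockResponse(u, spec, lagSamples = round(spec$deoxyLagSec * fs))

  set.seed(spec$seed)
  oxy <- matrix(0, n, spec$nChannels)
  deoxy <- matrix(0, n, spec$nChannels)
  for (c in seq_len(spec$nChannels)) {
    a <- spec$channelAmplitudes[c]
    oxy[, c] <- a * respOxy + .driftTrace(n, fs, spec) +
      stats::rnorm(n, 0, spec$noiseSd)
    deoxy[, c] <- spec$deoxyRatio * a * respDeoxy + .driftTrace(n, fs, spec) +
      stats::rnorm(n, 0, spec$noiseSd)
  }
  ids <- sprintf("ch%02d", seq_len(spec$nChannels))
  gt <- stats::setNames(spec$channelAmplitudes, ids)
  list(recording = NirsRecording(oxy, deoxy, fs, ids),
       events = events, groundTruth = gt)
}

#' Enumerate measurement channels of alternating emitter/detector patches
#'
#' In an optical-topography patch, emitters and detectors alternate on a
#' rectangular grid (checkerboard), so every pair of grid-adjacent probes is
#' an emitter-detector pair and forms one measurement channel. Two standard
#' 4x4 patches (16 probes each) therefore yield 48 channels.
#'
#' @param rows,cols patch grid dimensions
#' @param nPatches number of identical patches
#' @return data.frame with one row per channel: patch, probe grid positions
#'   of the emitter-side and detector-side probes
#' @examples
#' nrow(probeChannels(4, 4, 2))  # 48
#' @export
probeChannels <- function(rows = 4, cols = 4, nPatches = 1) {
  pairs <- list()
  for (r in seq_len(rows)) for (cc in seq_len(cols)) {
    if (cc < cols) pairs[[length(pairs) + 1]] <- c(r, cc, r, cc + 1)
    if (r < rows) pairs[[length(pairs) + 1]] <- c(r, cc, r + 1, cc)
  }
  one <- do.call(rbind, pairs)
  out <- do.call(rbind, lapply(seq_len(nPatches), function(p)
    data.frame(patch = p, r1 = one[, 1], c1 = one[, 2],
               r2 = one[, 3], c2 = one[, 4])))
  rownames(out) <- NULL
  out
}

#' Simulate a cohort of recordings
#'
#' Produces independent synthetic participants sharing the block design but
#' differing in their random seeds, so group-level pipeline comparisons can
#' be run end to end.
#'
#' @param nRecordings number of synthetic participants
#' @param seed master seed; participant r uses \code{seed * 1000 + r}
#' @param ... overrides passed to \code{\link{simulationSpec}}
#' @return list of \code{generateRecording} results, one per participant
#' @export
simulateCohort <- function(nRecordings = 6, seed = 1L, ...) {
  lapply(seq_len(nRecordings), function(r) {
    generateRecording(simulationSpec(seed = as.integer(seed) * 1000L + r, ...))
  })
}
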
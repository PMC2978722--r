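.subsetFeatureRows <- function(fm, idx) {
  new("FeatureMatrix", X = featureValues(fm)[idx, , drop = FALSE],
      valid = validRows(fm)[idx], spec = fm@spec)
}

#' Decode one recording with one feature space
#'
#' Runs the full per-recording pipeline: EMA filtering, first-half/second-half
#' trial split, feature assembly (CBSI scale from the training range only),
#' SVM training on valid training rows, per-timepoint prediction, and
#' accuracy plus onset/offset delays on the test half.
#'
#' @param rec a \linkS4class{NirsRecording}
#' @param events the block schedule
#' @param spec the \linkS4class{FeatureSpec} to decode with
#' @param cfg a \code{\link{pipelineConfig}}
#' @param filtered set TRUE if \code{rec} is already EMA-filtered (lets
#'   sweeps filter once)
#' @return list with elements \code{model} (\linkS4class{TrainedModel}),
#'   \code{split}, \code{pred} (full-length +1/-1 vector), \code{labels},
#'   \code{accuracy} (test half, valid rows), \code{delays}
#'   (\linkS4class{DelayResult} on test blocks) and \code{features}
#' @examples
#' sim <- generateRecording(simulationSpec(nChannels = 2, nTrials = 4))
#' res <- decodeRecording(sim$recording, sim$events,
#'                        FeatureSpec("ch01", historySec = 1))
#' res$accuracy
#' @export
decodeRecording <- function(rec, events, spec, cfg = pipelineConfig(),
                            filtered = FALSE) {
  filt <- if (filtered) rec else filterRecording(rec, cfg)
  n <- nSamples(filt); fs <- samplingRate(filt); tz <- t0(filt)
  split <- splitTrials(events, n, fs, tz)
  trainIdx <- splitSamples(split, "train")
  testIdx <- splitSamples(split, "test")
  feats <- assembleFeatures(filt, spec, trainSamples = trainIdx)
  labels <- labelTimepoints(events, n, fs, tz)
  model <- trainClassifier(.subsetFeatureRows(feats, trainIdx),
                           labels[trainIdx], cost = cfg$svmCost,
                           scaleFeatures = cfg$scaleFeatures,
                           classWeights = cfg$classWeights)
  pred <- predict(model, feats)
  testEvents <- splitEvents(split, events, "test")
  acc <- classificationAccuracy(pred[testIdx], labels[testIdx],
                                validRows(feats)[testIdx])
  delays <- onsetOffsetDelays(pred, testEvents, fs, tz)
  list(model = model, split = split, pred = pred, labels = labels,
       accuracy = acc, delays = delays, features = feats)
}

.metricsRow <- function(value, res) {
  s <- delaySummary(res$delays)
  data.frame(value = I(value), accuracy = res$accuracy,
             onsetDelay = s$meanOnset, offsetDelay = s$meanOffset,
             onsetCensored = s$onsetCensored, offsetCensored = s$offsetCensored)
}

.makeSweep <- function(axisName, rows) {
  metrics <- do.call(rbind, rows)
  metrics$value <- unlist(metrics$value)
  opt <- metrics$value[which.max(metrics$accuracy)]
  new("SweepResult", axisName = axisName, metrics = metrics, optimum = opt)
}

# Rank channels on the training half of the (filtered) recording.
.trainingRanking <- function(filt, events, cfg) {
  split <- splitTrials(events, nSamples(filt), samplingRate(filt), t0(filt))
  rankChannels(filt, splitEvents(split, events, "train"),
               taskWindow = cfg$taskWindow, restWindow = cfg$restWindow,
               chromophore = cfg$rankChromophore, pooling = cfg$cnrPooling)
}

#' Sweep the history-window length
#'
#' Re-runs the decoder for each history length with everything else fixed
#' (top-CNR channel by default), collecting accuracy and delays.
#'
#' @param rec,events,cfg as in \code{\link{decodeRecording}}
#' @param historyValues history lengths in seconds
#' @param channels channel ids to use; default: the top-CNR training channel
#' @param signals,representation feature-space settings held fixed
#' @return a \linkS4class{SweepResult} over \code{historySec}
#' @export
sweepHistory <- function(rec, events, historyValues = c(0, 0.5, 1, 2),
                         cfg = pipelineConfig(), channels = NULL,
                         signals = "oxy", representation = "amplitude") {
  filt <- filterRecording(rec, cfg)
  if (is.null(channels))
    channels <- .trainingRanking(filt, events, cfg)$channel[1]
  rows <- lapply(historyValues, function(h) {
    res <- decodeRecording(filt, events,
                           FeatureSpec(channels, historySec = h,
                                       representation = representation,
                                       signals = signals),
                           cfg, filtered = TRUE)
    .metricsRow(h, res)
  })
  .makeSweep("historySec", rows)
}

#' Sweep the chromophore combination
#'
#' Decodes with each of the five combinations (oxy, deoxy, both, cbsi,
#' total) at a fixed history length. Delays of a combination whose accuracy
#' falls below \code{cfg$accuracyFloor} are reported as NA rather than as a
#' meaningless search over a failing classifier.
#'
#' @param rec,events,cfg as in \code{\link{decodeRecording}}
#' @param historySec fixed history length in seconds
#' @param channels channel ids; default: top-CNR training channel
#' @return a \linkS4class{SweepResult} over \code{signals}
#' @export
sweepSignals <- function(rec, events, historySec = 1,
                         cfg = pipelineConfig(), channels = NULL) {
  filt <- filterRecording(rec, cfg)
  if (is.null(channels))
    channels <- .trainingRanking(filt, events, cfg)$channel[1]
  combos <- c("oxy", "deoxy", "both", "cbsi", "total")
  rows <- lapply(combos, function(sg) {
    res <- decodeRecording(filt, events,
                           FeatureSpec(channels, historySec = historySec,
                                       signals = sg),
                           cfg, filtered = TRUE)
    row <- .metricsRow(sg, res)
    if (res$accuracy < cfg$accuracyFloor) {
      row$onsetDelay <- NA_real_; row$offsetDelay <- NA_real_
    }
    row
  })
  .makeSweep("signals", rows)
}

#' Sweep the number of CNR-ranked channels
#'
#' Ranks channels by CNR on the training half, then includes them one by one
#' in decreasing-CNR order, decoding at each count.
#'
#' @param rec,events,cfg as in \code{\link{decodeRecording}}
#' @param maxChannels largest channel count to try (<= number of channels)
#' @param historySec history length per channel
#' @param signals chromophore combination per channel
#' @return a \linkS4class{SweepResult} over \code{nChannels}; the optimum is
#'   the accuracy-maximizing count
#' @export
sweepChannels <- function(rec, events, maxChannels = nChannels(rec),
                          historySec = 1, signals = "both",
                          cfg = pipelineConfig()) {
  if (maxChannels > nChannels(rec))
    stop("maxChannels exceeds the number of channels")
  filt <- filterRecording(rec, cfg)
  ranking <- .trainingRanking(filt, events, cfg)
  rows <- lapply(seq_len(maxChannels), function(k) {
    res <- decodeRecording(filt, events,
                           FeatureSpec(ranking$channel[seq_len(k)],
                                       historySec = historySec,
                                       signals = signals),
                           cfg, filtered = TRUE)
    .metricsRow(k, res)
  })
  .makeSweep("nChannels", rows)
}

#' Compare the four canonical feature spaces on one recording
#'
#' Decodes with (1) the baseline single-channel, single-sample oxy feature
#' (a pure amplitude threshold), (2) the same channel with 1 s of history,
#' (3) history plus deoxy-Hb, and (4) the full space: history, both
#' chromophores, and the accuracy-maximizing number of CNR-ranked channels.
#'
#' @param rec,events,cfg as in \code{\link{decodeRecording}}
#' @param historySec history length for the non-baseline conditions
#' @param maxChannels largest channel count considered for the full space
#' @return data.frame with one row per condition: \code{condition},
#'   \code{accuracy}, \code{onsetDelay}, \code{offsetDelay},
#'   \code{nChannels}, censoring counts
#' @export
runFullPipeline <- function(rec, events, cfg = pipelineConfig(),
                            historySec = 1,
                            maxChannels = min(nChannels(rec), 12L)) {
  filt <- filterRecording(rec, cfg)
  ranking <- .trainingRanking(filt, events, cfg)
  top <- ranking$channel[1]
  one <- function(spec) decodeRecording(filt, events, spec, cfg, filtered = TRUE)
  conds <- list(
    baseline = one(FeatureSpec(top, historySec = 0, signals = "oxy")),
    history = one(FeatureSpec(top, historySec = historySec, signals = "oxy")),
    historyDeoxy = one(FeatureSpec(top, historySec = historySec,
                                   signals = "both"))
  )
  chanSweep <- sweepChannels(rec, events, maxChannels = maxChannels,
                             historySec = historySec, signals = "both",
                             cfg = cfg)
  bestK <- sweepOptimum(chanSweep)
  conds$full <- one(FeatureSpec(ranking$channel[seq_len(bestK)],
                                historySec = historySec, signals = "both"))
  nCh <- c(1L, 1L, 1L, as.integer(bestK))
  out <- do.call(rbind, Map(function(nm, res, k) {
    row <- .metricsRow(nm, res)
    names(row)[1] <- "condition"
    row$nChannels <- k
    row
  }, names(conds), conds, nCh))
  out$condition <- unlist(out$condition)
  rownames(out) <- NULL
  out
}

#' Group-level feature-space comparison on a cohort
#'
#' Runs \code{\link{runFullPipeline}} on each recording and aggregates the
#' per-recording metrics by condition (plain means; the aggregate of a
#' condition's delay is the mean of the per-recording mean delays over
#' recordings where it is defined).
#'
#' @param cohort list of \code{list(recording, events, ...)} elements, e.g.
#'   from \code{\link{simulateCohort}}
#' @param cfg,historySec,maxChannels passed to \code{\link{runFullPipeline}}
#' @return list with \code{perRecording} (data.frame, one row per recording
#'   x condition) and \code{aggregate} (one row per condition)
#' @export
runCohort <- function(cohort, cfg = pipelineConfig(), historySec = 1,
                      maxChannels = NULL) {
  per <- do.call(rbind, lapply(seq_along(cohort), function(r) {
    el <- cohort[[r]]
    mc <- if (is.null(maxChannels)) min(nChannels(el$recording), 12L)
    else maxChannels
    tab <- runFullPipeline(el$recording, el$events, cfg,
                           historySec = historySec, maxChannels = mc)
    cbind(recording = r, tab)
  }))
  agg <- do.call(rbind, lapply(split(per, per$condition), function(d)
    data.frame(condition = d$condition[1],
               accuracy = mean(d$accuracy),
               onsetDelay = mean(d$onsetDelay, na.rm = TRUE),
               offsetDelay = mean(d$offsetDelay, na.rm = TRUE),
               nRecordings = nrow(d))))
  agg <- agg[match(unique(per$condition), agg$condition), ]
  rownames(agg) <- NULL
  list(perRecording = per, aggregate = agg)
}
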
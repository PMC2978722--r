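test_that("accuracy counts valid matching samples", {
  truth <- rep(c(1L, -1L), 10)
  expect_equal(classificationAccuracy(truth, truth), 1)
  expect_equal(classificationAccuracy(-truth, truth), 0)
  pred <- truth; pred[c(1, 4, 9)] <- -pred[c(1, 4, 9)]
  expect_equal(classificationAccuracy(pred[1:10], truth[1:10]), 0.7)
  valid <- rep(c(TRUE, FALSE), 10)
  expect_equal(classificationAccuracy(pred, truth, valid),
               mean(pred[valid] == truth[valid]))
  expect_error(classificationAccuracy(pred, truth, rep(FALSE, 20)), "no valid")
})

test_that("delays are zero for a perfect detector and computed by index arithmetic", {
  ev <- EventSchedule(c(10, 40), 10, totalDuration = 70)
  truth <- labelTimepoints(ev, 700, 10)
  d <- onsetOffsetDelays(truth, ev, 10)
  expect_equal(onsetDelays(d), c(0, 0))
  expect_equal(offsetDelays(d), c(0, 0))

  # block onset at sample 101 (t = 10 s); first +1 at sample 141 -> 4.0 s
  pred <- rep(-1L, 700)
  pred[141:210] <- 1L
  d2 <- onsetOffsetDelays(pred, ev, 10)
  expect_equal(onsetDelays(d2)[1], 4.0)
  expect_equal(offsetDelays(d2)[1], 1.0)  # offset 20 s, first -1 at 21.0 s
})

test_that("an always-rest predictor censors every onset", {
  ev <- EventSchedule(c(10, 40), 10, totalDuration = 70)
  d <- onsetOffsetDelays(rep(-1L, 700), ev, 10)
  expect_true(all(is.na(onsetDelays(d))))
  expect_equal(offsetDelays(d), c(0, 0))
  expect_equal(censorCount(d), 2)
  s <- delaySummary(d)
  expect_equal(s$onsetCensored, 2)
  expect_true(is.na(s$meanOnset))
  expect_equal(s$meanOffset, 0)
})

test_that("delays are bounded by the trial interval and censoring is exhaustive", {
  set.seed(61)
  sim <- tinySim(nChannels = 2, nTrials = 4)
  res <- decodeRecording(sim$recording, sim$events,
                         FeatureSpec("ch01", historySec = 1))
  d <- res$delays
  nTest <- length(res$split@testBlocks)
  expect_length(onsetDelays(d), nTest)
  expect_length(offsetDelays(d), nTest)
  interval <- 30  # task + rest
  expect_true(all(onsetDelays(d) >= 0 & onsetDelays(d) < interval, na.rm = TRUE))
  expect_true(all(offsetDelays(d) >= 0 & offsetDelays(d) < interval, na.rm = TRUE))
})

test_that("always-rest accuracy equals the rest fraction in closed form", {
  sim <- tinySim(nChannels = 1, nTrials = 4)
  n <- nSamples(sim$recording)
  lab <- labelTimepoints(sim$events, n, 10)
  expect_equal(classificationAccuracy(rep(-1L, n), lab), mean(lab == -1L))
})

test_that("history sweep is structured, deterministic and directionally sane", {
  sim <- tinySim(seed = 3, nChannels = 2, nTrials = 6)
  one <- sweepHistory(sim$recording, sim$events, historyValues = 1)
  expect_equal(nrow(sweepMetrics(one)), 1)
  expect_equal(sweepOptimum(one), 1)

  sw <- sweepHistory(sim$recording, sim$events, historyValues = c(0, 1))
  m <- sweepMetrics(sw)
  expect_gte(m$accuracy[m$value == 1], m$accuracy[m$value == 0])

  sw2 <- sweepHistory(sim$recording, sim$events, historyValues = c(0, 1))
  expect_identical(sweepMetrics(sw2), m)
})

test_that("signal sweep covers the five combinations and total trails both", {
  sim <- tinySim(seed = 5, nChannels = 2, nTrials = 6)
  sw <- sweepSignals(sim$recording, sim$events, historySec = 1)
  m <- sweepMetrics(sw)
  expect_setequal(m$value, c("oxy", "deoxy", "both", "cbsi", "total"))
  expect_equal(nrow(m), 5)
  expect_lte(m$accuracy[m$value == "total"], m$accuracy[m$value == "both"])
})

test_that("oxy and deoxy decode near-identically on noiseless data", {
  sim <- generateRecording(simulationSpec(
    nChannels = 1, nTrials = 4, channelAmplitudes = 1, deoxyRatio = -1,
    noiseSd = 0, driftAmplitude = 0))
  sw <- sweepSignals(sim$recording, sim$events, historySec = 1,
                     channels = "ch01")
  m <- sweepMetrics(sw)
  expect_lt(abs(m$accuracy[m$value == "oxy"] - m$accuracy[m$value == "deoxy"]),
            0.02)
})

test_that("channel sweep is consistent at one channel and reports the argmax", {
  sim <- tinySim(seed = 9, nChannels = 4, nTrials = 4)
  cfg <- pipelineConfig()
  sw <- sweepChannels(sim$recording, sim$events, maxChannels = 3,
                      historySec = 1, signals = "both", cfg = cfg)
  m <- sweepMetrics(sw)
  expect_equal(m$value, 1:3)
  expect_equal(sweepOptimum(sw), m$value[which.max(m$accuracy)])

  filt <- filterRecording(sim$recording, cfg)
  split <- splitTrials(sim$events, nSamples(filt), samplingRate(filt))
  top <- rankChannels(filt, splitEvents(split, sim$events, "train"))$channel[1]
  single <- decodeRecording(filt, sim$events,
                            FeatureSpec(top, historySec = 1, signals = "both"),
                            cfg, filtered = TRUE)
  expect_equal(m$accuracy[1], single$accuracy)
  expect_error(sweepChannels(sim$recording, sim$events, maxChannels = 9),
               "exceeds")
})

test_that("adding true channels helps on average when several are active", {
  accs <- matrix(NA_real_, 10, 3)
  for (s in 1:10) {
    sim <- generateRecording(simulationSpec(
      nChannels = 12, nTrials = 8, seed = 100 + s,
      channelAmplitudes = c(1, 0.8, 0.6, rep(0, 9)), noiseSd = 0.35))
    sw <- sweepChannels(sim$recording, sim$events, maxChannels = 3,
                        historySec = 1, signals = "both")
    accs[s, ] <- sweepMetrics(sw)$accuracy
  }
  avg <- colMeans(accs)
  expect_true(all(diff(avg) >= -0.005))
})

test_that("the pipeline report has the four conditions and aggregates by mean", {
  cohort <- simulateCohort(2, seed = 6, nChannels = 3, nTrials = 4)
  out <- runCohort(cohort, maxChannels = 2)
  per <- out$perRecording; agg <- out$aggregate
  expect_setequal(unique(per$condition),
                  c("baseline", "history", "historyDeoxy", "full"))
  expect_equal(nrow(per), 8)
  expect_equal(nrow(agg), 4)
  for (cond in agg$condition) {
    expect_equal(agg$accuracy[agg$condition == cond],
                 mean(per$accuracy[per$condition == cond]))
  }
  expect_true(all(per$nChannels[per$condition == "baseline"] == 1))
})
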
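test_that("timepoint labels follow half-open block intervals", {
  ev <- EventSchedule(2, 1, totalDuration = 5)
  lab <- labelTimepoints(ev, 50, 10)
  expect_identical(which(lab == 1L), 21:30)  # samples at 2.0 <= t < 3.0
  expect_true(all(lab[-(21:30)] == -1L))

  empty <- EventSchedule(numeric(0), numeric(0), totalDuration = 5)
  expect_true(all(labelTimepoints(empty, 50, 10) == -1L))

  sim <- generateRecording(simulationSpec(nChannels = 1, nTrials = 10))
  lab10 <- labelTimepoints(sim$events, nSamples(sim$recording), 10)
  expect_equal(sum(lab10 == 1L), 10 * 100)   # 10 blocks x 10 s x 10 Hz

  expect_error(labelTimepoints(EventSchedule(4, 2, totalDuration = 6), 50, 10),
               "past the end")
})

test_that("trial split halves blocks with a ceiling rule and clean ranges", {
  ev10 <- EventSchedule(seq(20, by = 30, length.out = 10), 10,
                        totalDuration = 320)
  s10 <- splitTrials(ev10, 3200, 10)
  expect_identical(s10@trainBlocks, 1:5)
  expect_identical(s10@testBlocks, 6:10)
  # boundary at first test onset: 20 + 5*30 = 170 s -> sample 1701
  expect_identical(s10@trainRange, c(1L, 1701L))
  expect_identical(s10@testRange, c(1701L, 3201L))
  expect_length(intersect(splitSamples(s10, "train"), splitSamples(s10, "test")), 0)
  expect_identical(sort(c(splitSamples(s10, "train"), splitSamples(s10, "test"))),
                   1:3200)

  ev3 <- EventSchedule(c(10, 40, 70), 10, totalDuration = 100)
  s3 <- splitTrials(ev3, 1000, 10)
  expect_identical(s3@trainBlocks, 1:2)
  expect_identical(s3@testBlocks, 3L)
  expect_error(splitTrials(EventSchedule(10, 5, totalDuration = 100), 1000, 10),
               "at least 2")
})

test_that("a separable 1-D toy trains to a threshold inside the gap", {
  set.seed(51)
  x <- c(runif(60, -2, 0), runif(60, 1, 3))
  y <- rep(c(-1, 1), each = 60)
  fm <- asFeatureMatrix(matrix(x, ncol = 1))
  model <- trainClassifier(fm, y, cost = 128)
  pred <- predict(model, fm)
  expect_equal(pred, as.integer(y))
  thr <- -modelBias(model) / modelWeights(model)
  expect_gt(thr, 0); expect_lt(thr, 1)
  expect_error(trainClassifier(fm, rep(1, 120)), "both classes")
})

test_that("duplicated feature columns leave predictions unchanged", {
  set.seed(52)
  X <- matrix(rnorm(200), 100, 2)
  y <- ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(100, 0, 0.4) > 0, 1, -1)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  m1 <- trainClassifier(asFeatureMatrix(X), y)
  m2 <- trainClassifier(asFeatureMatrix(cbind(X, X)), y)
  p1 <- predict(m1, asFeatureMatrix(X))
  p2 <- predict(m2, asFeatureMatrix(cbind(X, X)))
  expect_gte(mean(p1 == p2), 0.99)
})

test_that("flipping labels negates the decision function", {
  set.seed(53)
  X <- matrix(rnorm(160), 80, 2)
  y <- ifelse(X[, 1] > 0.2, 1, -1)
  fm <- asFeatureMatrix(X)
  m <- trainClassifier(fm, y)
  mFlip <- trainClassifier(fm, -y)
  dv <- drop(X %*% modelWeights(m)) + modelBias(m)
  dvFlip <- drop(X %*% modelWeights(mFlip)) + modelBias(mFlip)
  expect_equal(dvFlip, -dv, tolerance = 1e-4)
})

test_that("prediction maps zero decision values to rest and ignores row order", {
  model <- toyModel(w = 1, b = 0)
  fm <- asFeatureMatrix(matrix(c(-1, 0, 2), ncol = 1))
  expect_identical(predict(model, fm), c(-1L, -1L, 1L))
  set.seed(54)
  X <- matrix(rnorm(60), 30, 2)
  m2 <- toyModel(w = c(1, -2), b = 0.3)
  perm <- sample(30)
  p <- predict(m2, asFeatureMatrix(X))
  pPerm <- predict(m2, asFeatureMatrix(X[perm, ]))
  expect_identical(pPerm, p[perm])
  expect_error(predict(m2, asFeatureMatrix(X[, 1, drop = FALSE])), "mismatch")
})

test_that("invalid rows are emitted as rest and excluded from training", {
  set.seed(55)
  X <- matrix(rnorm(40), 20, 2)
  valid <- rep(c(FALSE, TRUE), c(5, 15))
  fm <- asFeatureMatrix(X, valid)
  model <- toyModel(w = c(10, 10), b = 100)  # everything positive when valid
  expect_true(all(predict(model, fm)[1:5] == -1L))
  # corrupt invalid rows: the trained model must not change
  y <- rep(c(-1, 1), 10)
  m1 <- trainClassifier(fm, y)
  X2 <- X; X2[1:5, ] <- 1e6
  m2 <- trainClassifier(asFeatureMatrix(X2, valid), y)
  expect_equal(modelWeights(m1), modelWeights(m2))
})

test_that("corrupting test-range samples leaves the trained model untouched", {
  sim <- tinySim(nChannels = 2, nTrials = 4)
  cfg <- pipelineConfig()
  spec <- FeatureSpec("ch01", historySec = 1, signals = "cbsi")
  res <- decodeRecording(sim$recording, sim$events, spec, cfg)
  testIdx <- splitSamples(res$split, "test")
  o <- oxyHb(sim$recording); d <- deoxyHb(sim$recording)
  o[testIdx, ] <- o[testIdx, ] + 50; d[testIdx, ] <- d[testIdx, ] - 50
  recMut <- NirsRecording(o, d, samplingRate(sim$recording),
                          channelIds(sim$recording))
  resMut <- decodeRecording(recMut, sim$events, spec, cfg)
  expect_identical(modelWeights(resMut$model), modelWeights(res$model))
  expect_identical(modelBias(resMut$model), modelBias(res$model))
})

test_that("decoding is deterministic given seed and config", {
  a <- decodeRecording(tinySim(seed = 77)$recording, tinySim(seed = 77)$events,
                       FeatureSpec("ch01", historySec = 0.5))
  b <- decodeRecording(tinySim(seed = 77)$recording, tinySim(seed = 77)$events,
                       FeatureSpec("ch01", historySec = 0.5))
  expect_identical(a$pred, b$pred)
  expect_identical(modelWeights(a$model), modelWeights(b$model))
})

test_that("history features beat the always-rest baseline on clean data", {
  sim <- generateRecording(simulationSpec(nChannels = 1, nTrials = 4,
                                          channelAmplitudes = 1,
                                          noiseSd = 0, driftAmplitude = 0))
  res <- decodeRecording(sim$recording, sim$events,
                         FeatureSpec("ch01", historySec = 1))
  testIdx <- splitSamples(res$split, "test")
  restFrac <- mean(res$labels[testIdx] == -1L)
  expect_gt(res$accuracy, restFrac)
})
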
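test_that("finite differences of a line are its slope and zero curvature", {
  x <- 3 * (1:20)
  g1 <- signalGradient(x, 1)
  g2 <- signalGradient(x, 2)
  expect_true(all(g1[-1] == 3))
  expect_true(is.na(g1[1]))
  expect_true(all(g2[-(1:2)] == 0))
  expect_true(all(is.na(g2[1:2])))
})

test_that("second-order gradient composes from first order and matches a loop oracle", {
  set.seed(21)
  x <- rnorm(100)
  gg <- signalGradient(signalGradient(x, 1), 1)
  g2 <- signalGradient(x, 2)
  expect_equal(gg[-(1:2)], g2[-(1:2)])
  # naive two-loop differencing
  d1 <- numeric(100); d2 <- numeric(100)
  for (t in 2:100) d1[t] <- x[t] - x[t - 1]
  for (t in 3:100) d2[t] <- d1[t] - d1[t - 1]
  expect_equal(signalGradient(x, 1)[-1], d1[-1], tolerance = 1e-15)
  expect_equal(g2[-(1:2)], d2[-(1:2)], tolerance = 1e-15)
  expect_error(signalGradient(c(1, 2), 2), "too short")
})

test_that("CBSI correction handles exact (anti-)correlation", {
  set.seed(22)
  x <- rnorm(50)
  expect_equal(cbsiCorrect(x, -x), x)        # alpha = 1, (x + x)/2
  expect_equal(cbsiCorrect(x, x), rep(0, 50))
  expect_error(cbsiCorrect(x, rep(1, 50)), "zero variance")
})

test_that("CBSI improves correlation with the clean signal under common-mode noise", {
  tt <- seq(0, 60, by = 0.1)
  ref <- sin(2 * pi * tt / 15)
  wins <- 0; n <- 100
  for (s in seq_len(n)) {
    set.seed(s)
    common <- 0.8 * rnorm(length(tt))
    oxy <- ref + common + 0.1 * rnorm(length(tt))
    deoxy <- -ref + common + 0.1 * rnorm(length(tt))
    corrected <- cbsiCorrect(oxy, deoxy)
    wins <- wins + (stats::cor(corrected, ref) >= stats::cor(oxy, ref))
  }
  expect_gte(wins, 0.95 * n)
})

test_that("total hemoglobin is the commutative elementwise sum", {
  expect_equal(totalHb(c(1, 2), c(0.5, -1)), c(1.5, 1))
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(totalHb(x, y), totalHb(y, x))
  expect_equal(totalHb(x, -x), rep(0, 10))
  expect_error(totalHb(1:3, 1:2), "mismatch")
})

test_that("feature dimensions follow (y+1) x signals x channels", {
  sim <- tinySim(nChannels = 3, nTrials = 2)
  rec <- filterRecording(sim$recording)
  fm <- assembleFeatures(rec, FeatureSpec("ch01", historySec = 2))
  expect_equal(ncol(featureValues(fm)), 21)   # 2 s at 10 Hz, oxy only
  nsig <- c(oxy = 1, deoxy = 1, both = 2, total = 1, cbsi = 1)
  for (y in c(0, 3, 10)) for (sg in names(nsig)) for (k in 1:2) {
    fm <- assembleFeatures(rec, FeatureSpec(channelIds(rec)[seq_len(k)],
                                            historySec = y / 10, signals = sg))
    expect_equal(ncol(featureValues(fm)), (y + 1) * nsig[[sg]] * k)
  }
  # no-history degenerate case: every row valid
  fm0 <- assembleFeatures(rec, FeatureSpec(channelIds(rec), historySec = 0))
  expect_equal(ncol(featureValues(fm0)), 3)
  expect_true(all(validRows(fm0)))
  expect_error(assembleFeatures(rec, FeatureSpec("nope", historySec = 0)),
               "unknown channels")
})

test_that("amplitude rows are the brute-force history slice", {
  sim <- tinySim(nChannels = 2, nTrials = 2)
  rec <- filterRecording(sim$recording)
  y <- 5
  fm <- assembleFeatures(rec, FeatureSpec(c("ch01", "ch02"),
                                          historySec = y / 10, signals = "both"))
  X <- featureValues(fm)
  expect_false(any(validRows(fm)[1:y]))
  for (t in c(y + 1, 50, nSamples(rec))) {
    expect_true(validRows(fm)[t])
    slice <- c(oxyHb(rec)[t:(t - y), 1], deoxyHb(rec)[t:(t - y), 1],
               oxyHb(rec)[t:(t - y), 2], deoxyHb(rec)[t:(t - y), 2])
    expect_equal(unname(X[t, ]), slice)
  }
})

test_that("feature assembly is causal", {
  sim <- tinySim(nChannels = 1, nTrials = 2)
  rec <- filterRecording(sim$recording)
  fm <- assembleFeatures(rec, FeatureSpec("ch01", historySec = 1))
  o <- oxyHb(rec); o[201:nrow(o), ] <- 0
  recMut <- NirsRecording(o, deoxyHb(rec), samplingRate(rec), channelIds(rec))
  fmMut <- assembleFeatures(recMut, FeatureSpec("ch01", historySec = 1))
  expect_equal(featureValues(fm)[1:200, ], featureValues(fmMut)[1:200, ])
})

test_that("gradient features are an invertible linear map of amplitude features", {
  sim <- tinySim(nChannels = 1, nTrials = 2)
  rec <- filterRecording(sim$recording)
  y <- 4
  A <- featureValues(assembleFeatures(rec, FeatureSpec("ch01", historySec = y / 10)))
  G <- featureValues(assembleFeatures(rec, FeatureSpec("ch01", historySec = y / 10,
                                                       representation = "gradient1")))
  expect_equal(ncol(A), ncol(G))
  # map amplitude -> gradient: [x_t, x_t - x_{t-1}, ..., x_{t-y+1} - x_{t-y}]
  M <- matrix(0, y + 1, y + 1)
  M[1, 1] <- 1
  for (j in 1:y) { M[j + 1, j] <- 1; M[j + 1, j + 1] <- -1 }
  valid <- rowSums(A != 0) > 0 & rowSums(G != 0) > 0
  expect_equal(unname(G[valid, ]), unname(A[valid, ] %*% t(M)))
  expect_gt(abs(det(M)), 0)  # invertible, so the spaces are linearly equivalent
})

test_that("CBSI scale comes from the training range only", {
  sim <- tinySim(nChannels = 1, nTrials = 4)
  rec <- filterRecording(sim$recording)
  train <- 1:500
  fm <- assembleFeatures(rec, FeatureSpec("ch01", historySec = 0,
                                          signals = "cbsi"),
                         trainSamples = train)
  o <- oxyHb(rec); d <- deoxyHb(rec)
  alphaTrain <- cbsiAlpha(o[train, 1], d[train, 1])
  expect_equal(unname(featureValues(fm)[, 1]),
               (o[, 1] - alphaTrain * d[, 1]) / 2)
})
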
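#' Per-sample task/rest labels from a block schedule
#'
#' Sample k (1-based) at time \code{t0 + (k-1)/fs} is labeled +1 (task) if it
#' falls inside any half-open block interval \code{[onset, onset+duration)},
#' else -1 (rest). This is the behavioral ground truth, not the delayed
#' hemodynamic state.
#'
#' @param events an \linkS4class{EventSchedule}
#' @param n number of samples
#' @param fs sampling rate in Hz
#' @param t0 time of the first sample
#' @return integer vector of +1/-1 labels, length \code{n}
#' @export
labelTimepoints <- function(events, n, fs, t0 = 0) {
  tt <- t0 + (seq_len(n) - 1) / fs
  end <- t0 + n / fs
  if (nBlocks(events) && any(onsets(events) + durations(events) > end + 1e-9))
    stop("a block extends past the end of the recording")
  lab <- rep(-1L, n)
  for (b in seq_len(nBlocks(events))) {
    o <- onsets(events)[b]
    lab[tt >= o & tt < o + durations(events)[b]] <- 1L
  }
  lab
}

#' First-half-train / second-half-test trial split
#'
#' The first \code{ceiling(nBlocks/2)} blocks are assigned to training and
#' the remainder to test. Each half keeps the rest period following its
#' blocks: the boundary sits at the first test block's onset, so the rest
#' period between the halves belongs to the training range. History windows
#' of early test rows may extend into training-range signal samples; signals
#' are past observations, not labels, so this matches causal deployment.
#'
#' @param events an \linkS4class{EventSchedule} (>= 2 blocks)
#' @param n number of samples
#' @param fs sampling rate in Hz
#' @param t0 time of the first sample
#' @return a \linkS4class{TrialSplit}
#' @export
splitTrials <- function(events, n, fs, t0 = 0) {
  nb <- nBlocks(events)
  if (nb < 2L) stop("need at least 2 blocks to split")
  n <- as.integer(n)
  nTrain <- as.integer(ceiling(nb / 2))
  firstTestOnset <- onsets(events)[nTrain + 1L]
  boundary <- which(t0 + (seq_len(n) - 1) / fs >= firstTestOnset - 1e-9)[1]
  if (is.na(boundary)) stop("test blocks lie outside the recording")
  new("TrialSplit",
      trainBlocks = seq_len(nTrain),
      testBlocks = seq.int(nTrain + 1L, nb),
      trainRange = c(1L, boundary),
      testRange = c(boundary, n + 1L))
}

#' @rdname splitTrials
#' @param split a \linkS4class{TrialSplit}
#' @param events the schedule the split was made from
#' @param which "train" or "test"
#' @return \code{splitEvents}: the \linkS4class{EventSchedule} restricted to
#'   one half; \code{splitSamples}: the integer sample indices of one half
#' @export
splitEvents <- function(split, events, which = c("train", "test")) {
  which <- match.arg(which)
  idx <- if (which == "train") split@trainBlocks else split@testBlocks
  EventSchedule(onsets(events)[idx], durations(events)[idx],
                totalDuration = totalDuration(events))
}

#' @rdname splitTrials
#' @export
splitSamples <- function(split, which = c("train", "test")) {
  which <- match.arg(which)
  r <- if (which == "train") split@trainRange else split@testRange
  seq.int(r[1], r[2] - 1L)
}

#' Train the linear soft-margin SVM decoder
#'
#' Fits a linear support vector machine (hinge loss, penalty C) on the valid
#' rows of the feature matrix, treating every time point as an instance
#' labeled +1 (task) or -1 (rest). The solver is libsvm (via e1071) with no
#' feature scaling unless requested; the fitted hyperplane is extracted into
#' a \linkS4class{TrainedModel} so prediction is an explicit
#' \code{sign(w . x + b)}.
#'
#' @param features a \linkS4class{FeatureMatrix} (training rows)
#' @param labels +1/-1 vector, one per feature row
#' @param cost soft-margin penalty C (default 128)
#' @param scaleFeatures z-score columns with training statistics
#' @param classWeights optional named weights (e.g. \code{c("1"=2,"-1"=1)})
#' @return a \linkS4class{TrainedModel}
#' @export
trainClassifier <- function(features, labels, cost = 128,
                            scaleFeatures = FALSE, classWeights = NULL) {
  stopifnot(is(features, "FeatureMatrix"))
  X <- featureValues(features)
  if (length(labels) != nrow(X)) stop("label length must match feature rows")
  keep <- validRows(features)
  X <- X[keep, , drop = FALSE]
  y <- labels[keep]
  if (ncol(X) == 0L) stop("empty feature matrix")
  if (nrow(X) < 2L || length(unique(y)) < 2L)
    stop("training data must contain both classes")

  center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  if (scaleFeatures) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[scale == 0] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  }

  yf <- factor(y, levels = c(1, -1))
  fit <- e1071::svm(X, yf, type = "C-classification", kernel = "linear",
                    cost = cost, scale = FALSE, class.weights = classWeights,
                    tolerance = 1e-6)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient the hyperplane so positive decision values mean class +1
  dv <- drop(X %*% w) + b
  predPlus <- predict(fit, X) == "1"
  if (mean((dv > 0) == predPlus) < 0.5) { w <- -w; b <- -b }
  # fold the z-scoring into the reported hyperplane
  w <- w / scale
  b <- b - sum(w * center)
  new("TrainedModel", weights = unname(w), bias = b, cost = cost,
      spec = features@spec, columnNames = colnames(featureValues(features)))
}

#' Predict per-timepoint labels
#'
#' Applies the linear rule \code{sign(w . x + b)} to every valid row; a
#' decision value of exactly 0 maps to -1. Invalid rows (incomplete history)
#' are emitted as -1; the valid mask identifies them.
#'
#' @param object a \linkS4class{TrainedModel}
#' @param features a \linkS4class{FeatureMatrix} with matching columns
#' @return integer vector of +1/-1 labels, one per feature row
#' @export
setMethod("predict", "TrainedModel", function(object, features) {
  stopifnot(is(features, "FeatureMatrix"))
  X <- featureValues(features)
  if (ncol(X) != length(object@weights))
    stop(sprintf("feature dimension mismatch: model has %d, matrix has %d",
                 length(object@weights), ncol(X)))
  dv <- drop(X %*% object@weights) + object@bias
  out <- ifelse(dv > 0, 1L, -1L)
  out[!validRows(features)] <- -1L
  as.integer(out)
})
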
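# Small fixtures shared across test files; everything is built in code.

# A tiny, fast simulation for structural tests.
tinySim <- function(seed = 7, nChannels = 3, nTrials = 4, ...) {
  generateRecording(simulationSpec(nChannels = nChannels, nTrials = nTrials,
                                   seed = seed, ...))
}

# Wrap a plain matrix as a FeatureMatrix with all rows valid.
asFeatureMatrix <- function(X, valid = rep(TRUE, nrow(X))) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  new("FeatureMatrix", X = X, valid = valid,
      spec = FeatureSpec("toy", historySec = 0))
}

# A hand-built linear model for prediction-rule tests.
toyModel <- function(w, b) {
  new("TrainedModel", weights = w, bias = b, cost = 1,
      spec = FeatureSpec("toy", historySec = 0),
      columnNames = paste0("f", seq_along(w)))
}

# Reference EMA: the literal recursion M(t) = lambda x(t) + (1-lambda) M(t-1).
emaLoopOracle <- function(x, alpha, rule = "standard") {
  lambda <- if (rule == "standard") 2 / (alpha + 1) else 1 / alpha
  m <- numeric(length(x))
  m[1] <- x[1]
  for (t in seq_along(x)[-1]) m[t] <- lambda * x[t] + (1 - lambda) * m[t - 1]
  m
}
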
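#' Pipeline configuration
#'
#' Bundles every tunable parameter of the decoding pipeline with its default.
#' Defaults follow the reference protocol: EMA spans of 100 (long) and 20
#' (short) samples, CNR task window 6-12 s after block onset and rest window
#' -5-0 s before it, soft-margin penalty C = 128, and a first-half-train /
#' second-half-test trial split.
#'
#' @param emaAlphaLong long-term EMA span in samples (> 1)
#' @param emaAlphaShort short-term EMA span in samples (> 1, < emaAlphaLong)
#' @param lambdaRule EMA smoothing-factor convention: "standard"
#'   (lambda = 2/(alpha+1)) or "reciprocal" (lambda = 1/alpha)
#' @param taskWindow CNR task window (start, end) in seconds relative to
#'   block onset, half-open
#' @param restWindow CNR rest window (start, end) in seconds relative to
#'   block onset, half-open
#' @param cnrPooling "samples" pools raw samples across blocks (default);
#'   "blockmean" computes the pooled SD over block-averaged traces
#' @param rankChromophore chromophore used for CNR channel ranking
#' @param svmCost soft-margin penalty C (> 0)
#' @param scaleFeatures z-score features with training-set statistics
#'   (default FALSE: features enter the classifier unscaled)
#' @param classWeights optional named class weights passed to the solver
#'   (default NULL: no class weighting despite the 1:2 task/rest imbalance)
#' @param accuracyFloor sweep over chromophore combinations reports delays
#'   only for combinations whose accuracy reaches this floor
#' @param seed integer seed recorded with the configuration
#' @return a list with class \code{"PipelineConfig"}
#' @examples
#' cfg <- pipelineConfig()
#' cfg$svmCost
#' @export
pipelineConfig <- function(emaAlphaLong = 100, emaAlphaShort = 20,
                           lambdaRule = c("standard", "reciprocal"),
                           taskWindow = c(6, 12), restWindow = c(-5, 0),
                           cnrPooling = c("samples", "blockmean"),
                           rankChromophore = c("oxy", "deoxy"),
                           svmCost = 128, scaleFeatures = FALSE,
                           classWeights = NULL, accuracyFloor = 0.7,
                           seed = 1L) {
  lambdaRule <- match.arg(lambdaRule)
  cnrPooling <- match.arg(cnrPooling)
  rankChromophore <- match.arg(rankChromophore)
  stopifnot(
    emaAlphaLong > 1, emaAlphaShort > 1, emaAlphaShort < emaAlphaLong,
    length(taskWindow) == 2, taskWindow[1] < taskWindow[2],
    length(restWindow) == 2, restWindow[1] < restWindow[2],
    svmCost > 0
  )
  structure(list(
    emaAlphaLong = emaAlphaLong, emaAlphaShort = emaAlphaShort,
    lambdaRule = lambdaRule,
    taskWindow = as.numeric(taskWindow), restWindow = as.numeric(restWindow),
    cnrPooling = cnrPooling, rankChromophore = rankChromophore,
    svmCost = svmCost, scaleFeatures = isTRUE(scaleFeatures),
    classWeights = classWeights, accuracyFloor = accuracyFloor,
    seed = as.integer(seed)
  ), class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys missing from the file keep their \code{\link{pipelineConfig}}
#' defaults; unknown keys are an error.
#'
#' @param path path to a YAML or JSON file
#' @return a \code{PipelineConfig}
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, vals)
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig:\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-16s %s\n", k,
                if (is.null(v)) "NULL" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}

.log <- function(..., verbose = getOption("nirsdecode.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[nirsdecode] ", sprintf(...))
  invisible(NULL)
}
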
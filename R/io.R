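.sniffSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  if (lengths(regmatches(first, gregexpr("\t", first))) >
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

# Read one wide signal file into a time x channel matrix.
# Accepts time-major (header = channel ids) or channel-major (first column
# holds channel ids) layouts; the two yield identical results.
.readSignalMatrix <- function(path, naAction = c("reject", "interpolate")) {
  naAction <- match.arg(naAction)
  if (!file.exists(path)) stop("signal file not found: ", path)
  sep <- .sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 0L || nrow(df) == 0L) stop("no data in ", path)
  firstCol <- df[[1]]
  if (is.character(firstCol)) {
    # channel-major: rows are channels, first column their ids
    ids <- firstCol
    m <- t(as.matrix(df[, -1, drop = FALSE]))
    dimnames(m) <- list(NULL, ids)
  } else {
    # time-major: header names are the channel ids
    ids <- colnames(df)
    if (all(!is.na(suppressWarnings(as.numeric(ids)))))
      stop("missing header row in ", path,
           ": column names are all numeric, expected channel ids")
    m <- as.matrix(df)
  }
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) & !is.na(m))
    stop("non-numeric cells in ", path,
         if (length(bad)) sprintf(" (first at flat index %d)", bad[1]) else "")
  }
  if (anyNA(m) || any(!is.finite(m))) {
    if (naAction == "reject")
      stop("NaN/Inf or missing values in ", path,
           " (set naAction = \"interpolate\" to impute linearly)")
    m[!is.finite(m)] <- NA
    m <- apply(m, 2L, function(col) {
      if (anyNA(col)) {
        ok <- which(!is.na(col))
        if (length(ok) < 2L) stop("cannot interpolate: fewer than 2 finite samples")
        col <- stats::approx(ok, col[ok], xout = seq_along(col), rule = 2)$y
      }
      col
    })
  }
  m
}

#' Read a two-file wide-format recording
#'
#' Each file holds one chromophore as a delimited table, either time-major
#' (one column per channel, header row of channel ids) or channel-major (one
#' row per channel, ids in the first column); the orientation is detected
#' from the header and both yield the identical recording.
#'
#' @param pathOxy,pathDeoxy paths to the oxy-Hb and deoxy-Hb files
#' @param samplingRate sampling rate in Hz
#' @param t0 time of the first sample in seconds
#' @param naAction "reject" (default) fails on missing/non-finite values;
#'   "interpolate" fills them by per-channel linear interpolation
#' @return a \linkS4class{NirsRecording}
#' @seealso \code{\link{writeRecording}}, \code{\link{readRecordingLong}}
#' @export
readRecording <- function(pathOxy, pathDeoxy, samplingRate, t0 = 0,
                          naAction = c("reject", "interpolate")) {
  naAction <- match.arg(naAction)
  oxy <- .readSignalMatrix(pathOxy, naAction)
  deoxy <- .readSignalMatrix(pathDeoxy, naAction)
  if (nrow(oxy) != nrow(deoxy))
    stop(sprintf("sample count mismatch: %s has %d samples, %s has %d",
                 pathOxy, nrow(oxy), pathDeoxy, nrow(deoxy)))
  if (!identical(colnames(oxy), colnames(deoxy))) {
    if (!setequal(colnames(oxy), colnames(deoxy)))
      stop("channel id mismatch between ", pathOxy, " and ", pathDeoxy)
    deoxy <- deoxy[, colnames(oxy), drop = FALSE]
  }
  NirsRecording(oxy, deoxy, samplingRate, colnames(oxy), t0)
}

#' Read a long-format recording
#'
#' Expects columns \code{time}, \code{channel}, \code{oxy}, \code{deoxy}
#' (any order); every channel must be sampled at every time point.
#'
#' @param path delimited file with the four long-format columns
#' @param samplingRate sampling rate in Hz; inferred from the time column
#'   when omitted
#' @return a \linkS4class{NirsRecording}
#' @export
readRecordingLong <- function(path, samplingRate = NULL) {
  sep <- .sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("time", "channel", "oxy", "deoxy")
  if (!all(need %in% names(df)))
    stop("long-format file ", path, " must have columns: ",
         paste(need, collapse = ", "))
  tGrid <- sort(unique(df$time))
  ids <- unique(df$channel)
  if (nrow(df) != length(tGrid) * length(ids))
    stop("long-format file ", path, " is not a complete time x channel grid")
  if (is.null(samplingRate)) {
    dt <- diff(tGrid)
    if (length(dt) == 0L || max(abs(dt - dt[1])) > 1e-6 * dt[1])
      stop("cannot infer sampling rate from irregular time column in ", path)
    samplingRate <- 1 / dt[1]
  }
  key <- function(ch) df$channel == ch
  ord <- order(df$time)
  df <- df[ord, ]
  oxy <- vapply(ids, function(ch) df$oxy[key(ch)], numeric(length(tGrid)))
  deoxy <- vapply(ids, function(ch) df$deoxy[key(ch)], numeric(length(tGrid)))
  NirsRecording(oxy, deoxy, samplingRate, ids, t0 = tGrid[1])
}

#' Write a recording as two time-major CSV files
#'
#' Values are written with 17 significant digits so that
#' \code{readRecording(writeRecording(x))} is value-preserving.
#'
#' @param rec a \linkS4class{NirsRecording}
#' @param pathOxy,pathDeoxy output paths
#' @return invisibly, the two paths
#' @export
writeRecording <- function(rec, pathOxy, pathDeoxy) {
  writeOne <- function(m, path) {
    lines <- c(paste(channelIds(rec), collapse = ","),
               apply(m, 1L, function(r)
                 paste(sprintf("%.17g", r), collapse = ",")))
    writeLines(lines, path)
  }
  writeOne(oxyHb(rec), pathOxy)
  writeOne(deoxyHb(rec), pathDeoxy)
  invisible(c(pathOxy, pathDeoxy))
}

#' Read a block schedule from JSON or CSV
#'
#' JSON input is a list of \code{{"onset": ..., "duration": ...}} objects;
#' CSV input has columns \code{onset} and \code{duration}. Blocks may appear
#' in any order; overlaps or non-positive durations are validation errors.
#'
#' @param path path to the events file
#' @param totalDuration recording duration in seconds (defaults to the end
#'   of the last block)
#' @return an \linkS4class{EventSchedule}
#' @export
readEvents <- function(path, totalDuration = NULL) {
  if (!file.exists(path)) stop("events file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lst <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.data.frame(lst)) df <- lst
    else df <- do.call(rbind.data.frame, lst)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = .sniffSep(path))
  }
  if (!all(c("onset", "duration") %in% names(df)))
    stop("events file ", path, " must provide onset and duration")
  EventSchedule(df$onset, df$duration, totalDuration)
}

#' Write a block schedule to JSON
#'
#' @param events an \linkS4class{EventSchedule}
#' @param path output path
#' @return invisibly, the path
#' @export
writeEvents <- function(events, path) {
  jsonlite::write_json(
    data.frame(onset = onsets(events), duration = durations(events)),
    path, digits = NA)
  invisible(path)
}
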
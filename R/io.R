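# Reading and writing recordings, event schedules and result reports.
#
# The on-disk recording format is a delimited time-by-channel matrix (comma or
# tab separated, header row of channel ids) plus a JSON sidecar carrying the
# metadata that the matrix cannot: sampling frequency, chromophore,
# wavelengths and an optional montage.  Time is implicit: row i (1-based) is
# sample i-1 at (i-1)/fs seconds.

.sidecarPath <- function(path) paste0(path, ".meta.json")

.detectSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Load a multichannel fNIRS recording
#'
#' Reads a delimited time-by-channel matrix together with its JSON metadata
#' sidecar (written by [writeRecording()]; fields \code{fs},
#' \code{chromophore}, optionally \code{wavelengths}, \code{channel_ids} and
#' \code{montage}).  NaN or missing cells in the matrix are a data error and
#' the offending channel is named.
#'
#' SNIRF (HDF5) input is not supported by this build; convert such files to
#' the delimited format first.
#'
#' @param path path to the data file.
#' @param format \code{"delimited"} (the supported format) or \code{"snirf"}.
#' @param metaPath path to the JSON sidecar; defaults to
#'   \code{paste0(path, ".meta.json")}.
#' @return An [NirsRecording-class].
#' @seealso [writeRecording()], [loadEvents()]
#' @export
loadRecording <- function(path, format = c("delimited", "snirf"),
                          metaPath = .sidecarPath(path)) {
  format <- match.arg(format)
  if (format == "snirf")
    stop("SNIRF input is not supported by this build; ",
         "export the recording as a delimited matrix with a JSON sidecar")
  if (!file.exists(path)) stop("recording file not found: ", path)
  if (!file.exists(metaPath)) stop("metadata sidecar not found: ", metaPath)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (is.null(meta$fs) || is.null(meta$chromophore))
    stop("sidecar must provide 'fs' and 'chromophore'")
  tab <- utils::read.table(path, header = TRUE, sep = .detectSep(path),
                           check.names = FALSE, colClasses = "numeric")
  data <- as.matrix(tab)
  if (anyNA(data)) {
    bad <- colnames(data)[apply(is.na(data), 2L, any)]
    stop("NaN/missing values in channel(s): ", paste(bad, collapse = ", "))
  }
  montage <- NULL
  if (!is.null(meta$montage))
    montage <- as.data.frame(meta$montage)
  channelIds <- if (!is.null(meta$channel_ids)) meta$channel_ids else NULL
  NirsRecording(data, fs = meta$fs, chromophore = meta$chromophore,
                wavelengths = if (is.null(meta$wavelengths)) numeric()
                              else meta$wavelengths,
                channelIds = channelIds, montage = montage)
}

#' Write a recording as a delimited matrix plus JSON sidecar
#'
#' @param rec an [NirsRecording-class].
#' @param path output data file; \code{.tsv} extension writes tab-separated,
#'   anything else comma-separated.  The sidecar goes to
#'   \code{paste0(path, ".meta.json")}.
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "NirsRecording"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  d <- signalMatrix(rec)
  colnames(d) <- if (chromophore(rec) == "absorbance")
    paste0(rep(channelIds(rec), 2L), "@",
           rep(rec@wavelengths, each = nChannels(rec)))
  else channelIds(rec)
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  meta <- list(fs = fs(rec), chromophore = chromophore(rec),
               channel_ids = channelIds(rec))
  if (length(rec@wavelengths)) meta$wavelengths <- rec@wavelengths
  if (!is.null(montage(rec))) meta$montage <- montage(rec)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load an event schedule
#'
#' Reads a delimited table with columns \code{onset}, \code{duration},
#' \code{label} (seconds; see [EventSchedule-class]).  Rows are sorted by
#' onset; overlapping intervals or non-positive durations are validation
#' errors.  An empty table yields a valid empty schedule.
#'
#' @param path path to a comma- or tab-separated events table.
#' @return An [EventSchedule-class].
#' @export
loadEvents <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = .detectSep(path),
                           check.names = FALSE)
  need <- c("onset", "duration", "label")
  if (!all(need %in% names(tab)))
    stop("events table must have columns: ", paste(need, collapse = ", "))
  eventSchedule(tab$onset, tab$duration, as.character(tab$label))
}

#' Write an event schedule as a tab-separated table
#'
#' @param events an [EventSchedule-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEvents <- function(events, path) {
  stopifnot(is(events, "EventSchedule"))
  tab <- data.frame(onset = onsets(events), duration = durations(events),
                    label = trialLabels(events))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn writeReport per-channel scores, auxiliaries, mask and
#'   parameters of a selection result.
#' @export
setMethod("writeReport", "SelectionResult", function(x, path) {
  channels <- data.frame(id = x@channelIds, score = x@scores,
                         selected = x@selected)
  if (nrow(x@aux)) channels <- cbind(channels, x@aux)
  doc <- list(type = "selection", method = x@method, params = x@params,
              n_selected = sum(x@selected), channels = channels)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
})

#' @describeIn writeReport accuracy summaries, a comparisons array and the
#'   adjusted alpha of an evaluation report.
#' @export
setMethod("writeReport", "EvalReport", function(x, path) {
  doc <- list(type = "evaluation", adjusted_alpha = x@adjustedAlpha,
              accuracies = x@accuracies, comparisons = x@comparisons)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
})

#' Read back a JSON report written by writeReport
#'
#' @param path path to the JSON document.
#' @return The parsed report as a list (data frames for the tabular parts).
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Published benchmark classification accuracies
#'
#' Subject-wise two-class LOOCV accuracies (percent) published for a
#' 29-subject open-access motor-imagery / mental-arithmetic fNIRS benchmark,
#' for each channel-selection strategy.  Shipped with the package so that the
#' reported column averages and the paired method comparisons can be
#' recomputed from the printed table without the raw recordings.
#'
#' @return A data.frame in long format with columns \code{subject},
#'   \code{task} (\code{"MA"}, \code{"LMI"}, \code{"RMI"}), \code{method}
#'   (\code{"zscore"}, \code{"tvalue"}, \code{"allchannels"}) and
#'   \code{accuracy} (percent).
#' @examples
#' acc <- benchmarkAccuracies()
#' aggregate(accuracy ~ task + method, acc, mean)
#' @export
benchmarkAccuracies <- function() {
  path <- system.file("extdata", "benchmark_accuracies.csv",
                      package = "fnirsselect", mustWork = TRUE)
  wide <- utils::read.csv(path, check.names = FALSE)
  cols <- setdiff(names(wide), "subject")
  long <- do.call(rbind, lapply(cols, function(cn) {
    parts <- strsplit(cn, "_", fixed = TRUE)[[1L]]
    data.frame(subject = wide$subject, task = parts[1L], method = parts[2L],
               accuracy = wide[[cn]])
  }))
  rownames(long) <- NULL
  long
}
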
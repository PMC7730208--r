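#' Accessors for package classes
#'
#' Small accessor generics: \code{fs} (sampling frequency, Hz),
#' \code{channelIds}, \code{chromophore}, \code{signalMatrix} (the
#' time-by-channel data), \code{montage}, \code{nChannels}, \code{nSamples},
#' \code{onsets}, \code{durations}, \code{trialLabels}, \code{nTrials},
#' \code{epochArray}, \code{epochWindow}, \code{channelScores},
#' \code{isSelected}, \code{selectionMethod}, \code{featureValues},
#' \code{classLabels}, \code{activeChannels}.
#'
#' @param x an object of one of the package classes.
#' @return The corresponding slot or derived quantity.
#' @name accessors
#' @aliases fs channelIds chromophore signalMatrix montage nChannels
#'   nSamples onsets durations trialLabels nTrials epochArray epochWindow
#'   channelScores isSelected selectionMethod featureValues classLabels
#'   activeChannels
#' @examples
#' rec <- NirsRecording(matrix(0:9, 5, 2), fs = 5)
#' fs(rec); channelIds(rec); nSamples(rec)
NULL

#' @rdname accessors
#' @export
setGeneric("fs", function(x) standardGeneric("fs"))
#' @rdname accessors
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))
#' @rdname accessors
#' @export
setGeneric("chromophore", function(x) standardGeneric("chromophore"))
#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setGeneric("montage", function(x) standardGeneric("montage"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("onsets", function(x) standardGeneric("onsets"))
#' @rdname accessors
#' @export
setGeneric("durations", function(x) standardGeneric("durations"))
#' @rdname accessors
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("epochArray", function(x) standardGeneric("epochArray"))
#' @rdname accessors
#' @export
setGeneric("epochWindow", function(x) standardGeneric("epochWindow"))
#' @rdname accessors
#' @export
setGeneric("channelScores", function(x) standardGeneric("channelScores"))
#' @rdname accessors
#' @export
setGeneric("isSelected", function(x) standardGeneric("isSelected"))
#' @rdname accessors
#' @export
setGeneric("selectionMethod", function(x) standardGeneric("selectionMethod"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("activeChannels", function(x) standardGeneric("activeChannels"))

#' Restrict an object to the selected channels
#'
#' @param x an [NirsRecording-class] or [EpochSet-class].
#' @param selection a [SelectionResult-class] whose channel count matches
#'   \code{x}, or \code{NULL} for the all-channels (no selection) arm.
#' @return An object of the same class containing only the selected channels,
#'   in their original order.
#' @export
setGeneric("applySelection",
           function(x, selection = NULL) standardGeneric("applySelection"))

#' Write a machine-readable JSON report
#'
#' Serializes a [SelectionResult-class] or [EvalReport-class] to a JSON
#' document (per-channel scores + mask + parameters, or accuracy summaries +
#' comparisons).  Output is byte-stable for identical inputs; read it back
#' with [readReport()].
#'
#' @param x the result object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
setGeneric("writeReport", function(x, path) standardGeneric("writeReport"))
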
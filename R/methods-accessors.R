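# Accessor and show methods.

#' @rdname accessors
#' @export
setMethod("fs", "NirsRecording", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("fs", "EpochSet", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("channelIds", "NirsRecording", function(x) x@channelIds)
#' @rdname accessors
#' @export
setMethod("channelIds", "EpochSet", function(x) x@channelIds)
#' @rdname accessors
#' @export
setMethod("channelIds", "SelectionResult", function(x) x@channelIds)
#' @rdname accessors
#' @export
setMethod("chromophore", "NirsRecording", function(x) x@chromophore)
#' @rdname accessors
#' @export
setMethod("signalMatrix", "NirsRecording", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("montage", "NirsRecording", function(x) x@montage)
#' @rdname accessors
#' @export
setMethod("nChannels", "NirsRecording", function(x) length(x@channelIds))
#' @rdname accessors
#' @export
setMethod("nChannels", "EpochSet", function(x) dim(x@epochs)[3L])
#' @rdname accessors
#' @export
setMethod("nChannels", "SelectionResult", function(x) length(x@scores))
#' @rdname accessors
#' @export
setMethod("nSamples", "NirsRecording", function(x) nrow(x@data))
#' @rdname accessors
#' @export
setMethod("nSamples", "EpochSet", function(x) dim(x@epochs)[2L])
#' @rdname accessors
#' @export
setMethod("onsets", "EventSchedule", function(x) x@onset)
#' @rdname accessors
#' @export
setMethod("durations", "EventSchedule", function(x) x@duration)
#' @rdname accessors
#' @export
setMethod("trialLabels", "EventSchedule", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("trialLabels", "EpochSet", function(x) x@trialLabels)
#' @rdname accessors
#' @export
setMethod("nTrials", "EventSchedule", function(x) length(x@onset))
#' @rdname accessors
#' @export
setMethod("nTrials", "EpochSet", function(x) dim(x@epochs)[1L])
#' @rdname accessors
#' @export
setMethod("epochArray", "EpochSet", function(x) x@epochs)
#' @rdname accessors
#' @export
setMethod("epochWindow", "EpochSet", function(x) x@window)
#' @rdname accessors
#' @export
setMethod("channelScores", "SelectionResult", function(x) {
  stats::setNames(x@scores, x@channelIds)
})
#' @rdname accessors
#' @export
setMethod("isSelected", "SelectionResult", function(x) {
  stats::setNames(x@selected, x@channelIds)
})
#' @rdname accessors
#' @export
setMethod("selectionMethod", "SelectionResult", function(x) x@method)
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("classLabels", "FeatureMatrix", function(x) x@classLabels)
#' @rdname accessors
#' @export
setMethod("activeChannels", "SimTruth", function(x) which(x@activeMask))

setMethod("show", "NirsRecording", function(object) {
  cat(sprintf("NirsRecording: %d samples x %d channels (%s), fs = %g Hz",
              nrow(object@data), length(object@channelIds),
              object@chromophore, object@fs))
  if (length(object@wavelengths))
    cat(sprintf(", wavelengths %s nm",
                paste(object@wavelengths, collapse = "/")))
  cat(sprintf("\n  duration %.1f s%s\n", nrow(object@data) / object@fs,
              if (is.null(object@montage)) "" else ", montage attached"))
})

setMethod("show", "EventSchedule", function(object) {
  n <- length(object@onset)
  cat(sprintf("EventSchedule: %d events", n))
  if (n) cat(sprintf(" (%s), first onset %.1f s, total task %.1f s",
                     paste(unique(object@label), collapse = ", "),
                     object@onset[1L], sum(object@duration)))
  cat("\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf(
    "EpochSet: %d trials x %d samples x %d channels, window [%g, %g) s, fs = %g Hz\n",
    d[1L], d[2L], d[3L], object@window[1L], object@window[2L], object@fs))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult (%s): %d / %d channels selected\n",
              object@method, sum(object@selected), length(object@selected)))
  if (sum(object@selected))
    cat("  selected:", paste(object@channelIds[object@selected],
                             collapse = " "), "\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d observations x %d features (%s)%s\n",
              nrow(object@values), ncol(object@values),
              paste(colnames(object@values), collapse = ", "),
              if (object@normalized) ", normalized" else ""))
  labs <- object@classLabels[nzchar(object@classLabels)]
  if (length(labs)) {
    tab <- table(labs)
    cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                            collapse = ", "), "\n")
  }
})

setMethod("show", "LDAModel", function(object) {
  cat(sprintf("LDAModel: %d features, classes %s vs %s, threshold %.4g\n",
              length(object@projection), object@classes[1L],
              object@classes[2L], object@threshold))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d / %d channels active (seed %d)\n",
              sum(object@activeMask), length(object@activeMask),
              as.integer(object@seed)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d accuracy summaries, %d comparisons, adjusted alpha %.4f\n",
              nrow(object@accuracies), nrow(object@comparisons),
              object@adjustedAlpha))
})
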
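#' @import methods
NULL

.CHROMOPHORES <- c("HbO", "HbR", "absorbance")

#' Multichannel fNIRS recording
#'
#' An \code{NirsRecording} holds a dense time-by-channel matrix of either
#' chromophore concentration changes (\eqn{\Delta}HbO or \eqn{\Delta}HbR, in
#' \eqn{\mu}M) or dual-wavelength absorbance changes (dimensionless), together
#' with the sampling frequency, channel labels and an optional 2-D montage.
#'
#' For \code{chromophore = "absorbance"} the matrix carries both wavelengths
#' side by side: the first half of the columns is wavelength 1, the second
#' half wavelength 2, in matched channel order (see [mbllConvert()]).
#'
#' Sample \code{i} (0-based) is taken at time \code{i/fs} seconds from
#' recording start.
#'
#' @slot data numeric matrix, time (rows) by channel (columns); no NA allowed.
#' @slot fs sampling frequency in Hz, positive scalar.
#' @slot chromophore one of \code{"HbO"}, \code{"HbR"}, \code{"absorbance"}.
#' @slot wavelengths numeric, the source wavelengths in nm (length 2 for
#'   absorbance recordings, empty otherwise).
#' @slot channelIds character, one label per physiological channel.
#' @slot montage optional \code{data.frame} with columns \code{x}, \code{y}
#'   giving 2-D head-schematic coordinates per channel, or \code{NULL}.
#'
#' @seealso [loadRecording()], [simulateRecording()]
#' @export
setClass("NirsRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    chromophore = "character",
    wavelengths = "numeric",
    channelIds = "character",
    montage = "ANY"
  ),
  prototype(montage = NULL)
)

setValidity("NirsRecording", function(object) {
  msg <- character()
  d <- object@data
  if (!is.numeric(d)) msg <- c(msg, "'data' must be a numeric matrix")
  if (nrow(d) < 2L) msg <- c(msg, "recording needs at least 2 samples")
  if (ncol(d) < 1L) msg <- c(msg, "recording needs at least 1 channel")
  if (anyNA(d)) msg <- c(msg, "'data' contains NA/NaN values")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(object@chromophore) != 1L ||
      !object@chromophore %in% .CHROMOPHORES)
    msg <- c(msg, sprintf("'chromophore' must be one of: %s",
                          paste(.CHROMOPHORES, collapse = ", ")))
  if (identical(object@chromophore, "absorbance")) {
    if (length(object@wavelengths) != 2L)
      msg <- c(msg, "absorbance recordings need exactly 2 wavelengths")
    if (ncol(d) %% 2L != 0L)
      msg <- c(msg, "absorbance recordings need an even column count (two wavelength blocks)")
    if (length(object@channelIds) != ncol(d) / 2L)
      msg <- c(msg, "'channelIds' must have one entry per physiological channel (half the columns)")
  } else {
    if (length(object@channelIds) != ncol(d))
      msg <- c(msg, "'channelIds' length must equal the channel count")
  }
  if (!is.null(object@montage)) {
    m <- object@montage
    if (!is.data.frame(m) || !all(c("x", "y") %in% names(m)) ||
        nrow(m) != length(object@channelIds))
      msg <- c(msg, "'montage' must be NULL or a data.frame with x, y rows matching channelIds")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an NirsRecording
#'
#' @param data time-by-channel numeric matrix.
#' @param fs sampling frequency (Hz).
#' @param chromophore \code{"HbO"}, \code{"HbR"} or \code{"absorbance"}.
#' @param wavelengths source wavelengths in nm (absorbance recordings only).
#' @param channelIds channel labels; defaults to the matrix column names or
#'   \code{"ch1"}, \code{"ch2"}, ...
#' @param montage optional data.frame of 2-D channel coordinates.
#' @return A validated [NirsRecording-class] object.
#' @examples
#' rec <- NirsRecording(matrix(rnorm(40), 20, 2), fs = 10)
#' nChannels(rec)
#' @export
NirsRecording <- function(data, fs, chromophore = "HbO",
                          wavelengths = numeric(), channelIds = NULL,
                          montage = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  nphys <- if (identical(chromophore, "absorbance")) ncol(data) %/% 2L else ncol(data)
  if (is.null(channelIds)) {
    channelIds <- if (!is.null(colnames(data)) &&
                      length(colnames(data)) == nphys)
      colnames(data) else paste0("ch", seq_len(nphys))
  }
  new("NirsRecording", data = data, fs = as.numeric(fs),
      chromophore = chromophore, wavelengths = as.numeric(wavelengths),
      channelIds = as.character(channelIds), montage = montage)
}

#' Task event schedule
#'
#' Onsets and durations are seconds from recording start; task intervals are
#' half-open \code{[onset, onset + duration)}.  Events must be sorted, strictly
#' increasing and non-overlapping.
#'
#' @slot onset numeric, task onsets (s).
#' @slot duration numeric, task durations (s), strictly positive.
#' @slot label character, task name per event.
#' @seealso [loadEvents()], [makeParadigm()], [boxcar()]
#' @export
setClass("EventSchedule",
  representation(onset = "numeric", duration = "numeric", label = "character")
)

setValidity("EventSchedule", function(object) {
  msg <- character()
  n <- length(object@onset)
  if (length(object@duration) != n || length(object@label) != n)
    msg <- c(msg, "onset, duration and label must have equal length")
  if (n > 0L) {
    if (any(!is.finite(object@onset)) || any(object@onset < 0))
      msg <- c(msg, "onsets must be finite and non-negative")
    if (any(!is.finite(object@duration)) || any(object@duration <= 0))
      msg <- c(msg, "durations must be strictly positive")
  }
  if (n > 1L) {
    if (any(diff(object@onset) <= 0))
      msg <- c(msg, "onsets must be strictly increasing")
    ends <- object@onset + object@duration
    if (length(msg) == 0L && any(ends[-n] > object@onset[-1L]))
      msg <- c(msg, "task intervals overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EventSchedule
#'
#' @param onset task onsets in seconds from recording start.
#' @param duration task durations in seconds.
#' @param label task names (recycled if a single string).
#' @return A validated [EventSchedule-class], sorted by onset.
#' @examples
#' eventSchedule(c(62, 89), 10, "task")
#' @export
eventSchedule <- function(onset = numeric(), duration = numeric(),
                          label = character()) {
  onset <- as.numeric(onset)
  duration <- as.numeric(duration)
  label <- as.character(label)
  n <- length(onset)
  if (n > 0L) {
    duration <- rep_len(duration, n)
    if (length(label) == 0L) label <- rep("task", n)
    label <- rep_len(label, n)
    ord <- order(onset)
    onset <- onset[ord]
    duration <- duration[ord]
    label <- label[ord]
  } else {
    duration <- numeric()
    label <- character()
  }
  new("EventSchedule", onset = as.numeric(onset), duration = duration,
      label = as.character(label))
}

#' Epoched trials
#'
#' A trial-by-time-by-channel array of signal segments cut around task onsets,
#' with the epoch window (seconds relative to onset, half-open), sampling
#' frequency, per-trial task labels and channel labels.
#'
#' @slot epochs numeric array, trial x time x channel.
#' @slot window numeric length 2, \code{c(start, end)} offsets in s.
#' @slot fs sampling frequency (Hz).
#' @slot trialLabels character, task label per trial.
#' @slot channelIds character, channel labels.
#' @seealso [epochTrials()], [averageTrials()]
#' @export
setClass("EpochSet",
  representation(epochs = "array", window = "numeric", fs = "numeric",
                 trialLabels = "character", channelIds = "character")
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L) msg <- c(msg, "'epochs' must be a 3-D array")
  else {
    if (d[2L] < 2L) msg <- c(msg, "epochs need at least 2 samples")
    if (length(object@trialLabels) != d[1L])
      msg <- c(msg, "'trialLabels' must match trial count")
    if (length(object@channelIds) != d[3L])
      msg <- c(msg, "'channelIds' must match channel count")
  }
  if (length(object@window) != 2L || diff(object@window) <= 0)
    msg <- c(msg, "'window' must be c(start, end) with end > start")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Channel-selection result
#'
#' Per-channel scores, auxiliary quantities and the boolean selection mask
#' produced by one of the three selection methods.  The primary score is the
#' z-score of the maximum cross-correlation (\code{"zscore"}), the robust-GLM
#' t-statistic (\code{"tvalue"}), or the task-minus-rest peak difference
#' (\code{"baseline"}).
#'
#' @slot method \code{"zscore"}, \code{"tvalue"} or \code{"baseline"}.
#' @slot scores numeric, primary score per channel.
#' @slot aux data.frame of per-channel auxiliaries (e.g. \code{r} and
#'   \code{lag} for zscore; \code{phi}, \code{psi}, \code{se}, \code{p} for
#'   tvalue; task/rest peaks for baseline).
#' @slot selected logical mask per channel.
#' @slot params list of the thresholds/options used.
#' @slot channelIds character, channel labels aligned with \code{scores}.
#' @seealso [zScoreSelect()], [tValueSelect()], [baselineSelect()]
#' @export
setClass("SelectionResult",
  representation(method = "character", scores = "numeric", aux = "data.frame",
                 selected = "logical", params = "list",
                 channelIds = "character")
)

setValidity("SelectionResult", function(object) {
  msg <- character()
  n <- length(object@scores)
  if (!object@method %in% c("zscore", "tvalue", "baseline"))
    msg <- c(msg, "unknown selection method")
  if (length(object@selected) != n || length(object@channelIds) != n)
    msg <- c(msg, "scores, selected and channelIds must have equal length")
  if (nrow(object@aux) != 0L && nrow(object@aux) != n)
    msg <- c(msg, "'aux' rows must match channel count")
  if (length(msg)) msg else TRUE
})

#' Trials-by-features matrix with class labels
#'
#' Rows are observations (one per trial and class), columns are features.
#' After [minmaxNormalize()] every column lies in [0, 1].
#'
#' @slot values numeric matrix, rows = observations, columns = features
#'   (named).
#' @slot classLabels character, class per row (\code{""} while unlabeled).
#' @slot normalized logical flag set by [minmaxNormalize()].
#' @seealso [extractFeatures()], [buildFeatureMatrix()], [ldaFit()]
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", classLabels = "character",
                 normalized = "logical")
)

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!is.numeric(object@values)) msg <- c(msg, "'values' must be numeric")
  if (length(object@classLabels) != nrow(object@values))
    msg <- c(msg, "'classLabels' must have one entry per row")
  if (is.null(colnames(object@values)))
    msg <- c(msg, "feature columns must be named")
  if (length(object@normalized) != 1L)
    msg <- c(msg, "'normalized' must be a single flag")
  if (length(msg)) msg else TRUE
})

#' Fitted Fisher discriminant
#'
#' Two-class Fisher LDA: the projection vector maximizing between-class over
#' within-class scatter, the per-class means, their projections and the
#' midpoint decision threshold (equal priors).
#'
#' @slot projection numeric weight vector.
#' @slot classMeans 2-by-d matrix of class mean vectors.
#' @slot classes character of length 2, in order of first appearance; ties on
#'   the projected axis go to \code{classes[1]}.
#' @slot threshold scalar decision point on the projected axis.
#' @slot projectedMeans numeric length 2.
#' @seealso [ldaFit()], [ldaPredict()]
#' @export
setClass("LDAModel",
  representation(projection = "numeric", classMeans = "matrix",
                 classes = "character", threshold = "numeric",
                 projectedMeans = "numeric")
)

setValidity("LDAModel", function(object) {
  msg <- character()
  if (length(object@classes) != 2L) msg <- c(msg, "exactly 2 classes required")
  if (!all(is.finite(object@projection)) ||
      all(object@projection == 0))
    msg <- c(msg, "projection must be finite and nonzero")
  if (nrow(object@classMeans) != 2L ||
      ncol(object@classMeans) != length(object@projection))
    msg <- c(msg, "classMeans must be 2 x length(projection)")
  if (length(msg)) msg else TRUE
})

#' Simulator ground truth
#'
#' Manifest of a synthetic session: which channels truly carry task-locked
#' activation, their amplitudes, the event schedule and the seed.
#'
#' @slot activeMask logical per channel.
#' @slot amplitudes numeric per channel (0 for inactive channels), in the
#'   units of the activation scaling (\eqn{\mu}M per unit template).
#' @slot events the [EventSchedule-class] of the session.
#' @slot seed integer seed that fixed all randomness.
#' @slot config the full simulation configuration list.
#' @seealso [simulateRecording()], [selectionMetrics()]
#' @export
setClass("SimTruth",
  representation(activeMask = "logical", amplitudes = "numeric",
                 events = "EventSchedule", seed = "numeric", config = "list")
)

setValidity("SimTruth", function(object) {
  if (length(object@activeMask) != length(object@amplitudes))
    "activeMask and amplitudes must have equal length" else TRUE
})

#' Method-comparison report
#'
#' Summary accuracies per method and task, pairwise paired-test comparisons,
#' and the Bonferroni-adjusted significance threshold.
#'
#' @slot accuracies data.frame with columns task, method, mean, sd, n.
#' @slot comparisons data.frame with columns task, method1, method2, t, p.
#' @slot adjustedAlpha Bonferroni-adjusted per-comparison alpha.
#' @seealso [evaluateAccuracies()], [writeReport()]
#' @export
setClass("EvalReport",
  representation(accuracies = "data.frame", comparisons = "data.frame",
                 adjustedAlpha = "numeric")
)
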
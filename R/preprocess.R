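# Physiological-noise filtering, smoothing, epoching and trial averaging.

#' Zero-phase Butterworth band-pass filter
#'
#' Removes physiological noise (cardiac, respiratory, very-low-frequency
#' drift) by a Butterworth band-pass applied forward and backward
#' (\code{filtfilt}), so the pass is zero-phase and introduces no latency that
#' would bias cross-correlation lags.  The effective magnitude response is
#' that of a filter of twice the nominal order.
#'
#' @param rec an [NirsRecording-class].
#' @param low,high passband edges in Hz; defaults 0.03-0.15 Hz, the band that
#'   retains task-locked hemodynamics while rejecting cardiac (~1 Hz) and
#'   respiratory (~0.25 Hz) components.
#' @param order nominal Butterworth order (default 4).
#' @return A filtered [NirsRecording-class] of identical shape.
#' @export
bandpassFilter <- function(rec, low = 0.03, high = 0.15, order = 4L) {
  stopifnot(is(rec, "NirsRecording"))
  nyq <- fs(rec) / 2
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("passband must satisfy 0 < low < high < fs/2 = %g Hz", nyq))
  n <- nSamples(rec)
  # filtfilt pads with 3 * (filter length); require a comfortable margin
  if (n <= 6L * (2L * order + 1L))
    stop("recording too short for the filter's warm-up")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  # the DC component is stop-band; removing the channel mean first keeps the
  # forward-backward pass free of slow edge transients
  out <- apply(signalMatrix(rec), 2L,
               function(x) signal::filtfilt(bf, x - mean(x)))
  initialize(rec, data = out)
}

#' Savitzky-Golay smoothing
#'
#' Per-channel polynomial smoothing.  A window of one sample is the identity;
#' the window length in samples is forced odd and must leave room for the
#' polynomial order.
#'
#' @param rec an [NirsRecording-class].
#' @param windowSeconds smoothing window length in seconds (default 1.0 s,
#'   i.e. 13 samples at 12.5 Hz after forcing odd).
#' @param polyorder polynomial order (default 3).
#' @return A smoothed [NirsRecording-class] of identical shape.
#' @export
savgolSmooth <- function(rec, windowSeconds = 1.0, polyorder = 3L) {
  stopifnot(is(rec, "NirsRecording"))
  n <- max(1L, round(windowSeconds * fs(rec)))
  if (n %% 2L == 0L) n <- n + 1L
  if (n == 1L) return(rec)
  if (n < polyorder + 2L) n <- polyorder + 2L + (polyorder %% 2L)
  if (n > nSamples(rec))
    stop("smoothing window longer than the recording")
  out <- apply(signalMatrix(rec), 2L,
               function(x) signal::sgolayfilt(x, p = polyorder, n = n))
  initialize(rec, data = out)
}

#' Cut trials into an epoch array
#'
#' Extracts, for every event, the samples in the half-open window
#' \code{[onset + window[1], onset + window[2])} seconds.  Every epoch has
#' \code{round(diff(window) * fs)} samples; at 12.5 Hz the default 24-s
#' analysis window gives 300 samples per trial.
#'
#' @param rec an [NirsRecording-class].
#' @param events an [EventSchedule-class].
#' @param window numeric \code{c(start, end)} offsets in seconds relative to
#'   task onset.
#' @return An [EpochSet-class] (trial x time x channel).
#' @export
epochTrials <- function(rec, events, window = c(0, 24)) {
  stopifnot(is(rec, "NirsRecording"), is(events, "EventSchedule"))
  if (nTrials(events) == 0L) stop("empty event schedule: nothing to epoch")
  k <- as.integer(round(diff(window) * fs(rec)))
  if (k < 2L) stop("epoch window must span at least 2 samples")
  start0 <- as.integer(round((onsets(events) + window[1L]) * fs(rec)))  # 0-based
  bad <- which(start0 < 0L | start0 + k > nSamples(rec))
  if (length(bad))
    stop("epoch window exceeds recording bounds for trial(s): ",
         paste(bad, collapse = ", "))
  nt <- nTrials(events)
  nc <- nChannels(rec)
  ep <- array(NA_real_, dim = c(nt, k, nc))
  d <- signalMatrix(rec)
  for (j in seq_len(nt))
    ep[j, , ] <- d[start0[j] + seq_len(k), , drop = FALSE]
  new("EpochSet", epochs = ep, window = as.numeric(window), fs = fs(rec),
      trialLabels = trialLabels(events), channelIds = channelIds(rec))
}

#' Average epochs over trials
#'
#' Element-wise mean over the trials of one stimulus type, giving the
#' trial-averaged response per channel that the selection methods operate on.
#'
#' @param ep an [EpochSet-class].
#' @param label task name to average over, or \code{NULL} for all trials.
#' @return A numeric time-by-channel matrix (columns named by channel).
#' @export
averageTrials <- function(ep, label = NULL) {
  stopifnot(is(ep, "EpochSet"))
  idx <- if (is.null(label)) seq_len(nTrials(ep))
         else which(trialLabels(ep) == label)
  if (!length(idx))
    stop("no epochs with label: ", label)
  m <- apply(ep@epochs[idx, , , drop = FALSE], c(2L, 3L), mean)
  colnames(m) <- channelIds(ep)
  m
}
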
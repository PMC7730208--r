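# Seeded synthetic fNIRS session generator with known ground-truth active
# channels, for end-to-end validation of the selection pipeline.

#' Simulation configuration
#'
#' Defines a synthetic single-task session: 60 s initial rest, \code{nTrials}
#' repetitions of (2 s cue + 10 s task + 15-17 s uniformly jittered rest),
#' 60 s final rest, 36 channels at 12.5 Hz.  Active channels carry a
#' task-locked hemodynamic response (task boxcar convolved with the
#' canonical two-gamma HRF, scaled by \code{activationAmplitude}); every
#' channel additionally carries physiological confounds: cardiac (~1.1 Hz),
#' respiratory (~0.25 Hz) and Mayer-wave (~0.1 Hz) sinusoids with seeded
#' random phases, a low-frequency random-walk drift, and white noise.  The
#' Mayer wave deliberately sits inside the 0.03-0.15 Hz analysis passband, so
#' selection must cope with an in-band confound.
#'
#' All amplitudes are in \eqn{\mu}M.  With the default
#' \code{activationAmplitude = 0.1} the convolved response plateaus near
#' 1 \eqn{\mu}M, a strong, clearly supra-noise (high-SNR) cortical
#' activation.
#'
#' @param nChannels number of channels (default 36).
#' @param fs sampling frequency in Hz (default 12.5).
#' @param nTrials number of task repetitions (default 20).
#' @param cueDuration,taskDuration cue and task lengths in seconds.
#' @param restRange inter-trial rest drawn uniformly from this range (s).
#' @param leadIn,leadOut initial/final rest (s).
#' @param nActive number of active channels sampled from the seeded stream
#'   when \code{activeChannels} is \code{NULL}.
#' @param activeChannels explicit integer indices of active channels, or
#'   \code{NULL}.
#' @param activationAmplitude scaling of the boxcar-convolved HRF on active
#'   channels (\eqn{\mu}M per unit template).
#' @param hbrRatio \eqn{\Delta}HbR is generated as \code{-hbrRatio} times
#'   the activation plus independent noise.
#' @param cardiacAmplitude,cardiacFreq,respAmplitude,respFreq,mayerAmplitude,mayerFreq
#'   sinusoidal confound amplitudes (\eqn{\mu}M) and frequencies (Hz).
#' @param driftSd per-sample standard deviation of the random-walk drift.
#' @param whiteSd white-noise standard deviation.
#' @param hrf HRF parameters from [hrfParams()].
#' @param seed integer seed fixing all randomness.
#' @return A validated configuration list of class \code{"fnirsSimConfig"}.
#' @seealso [simulateRecording()], [makeParadigm()]
#' @export
simConfig <- function(nChannels = 36L, fs = 12.5, nTrials = 20L,
                      cueDuration = 2, taskDuration = 10,
                      restRange = c(15, 17), leadIn = 60, leadOut = 60,
                      nActive = 8L, activeChannels = NULL,
                      activationAmplitude = 0.1, hbrRatio = 1 / 3,
                      cardiacAmplitude = 0.2, cardiacFreq = 1.1,
                      respAmplitude = 0.15, respFreq = 0.25,
                      mayerAmplitude = 0.05, mayerFreq = 0.1,
                      driftSd = 0.003, whiteSd = 0.05,
                      hrf = hrfParams(), seed = 1L) {
  cfg <- list(nChannels = as.integer(nChannels), fs = fs,
              nTrials = as.integer(nTrials), cueDuration = cueDuration,
              taskDuration = taskDuration, restRange = restRange,
              leadIn = leadIn, leadOut = leadOut,
              nActive = as.integer(nActive),
              activeChannels = activeChannels,
              activationAmplitude = activationAmplitude,
              hbrRatio = hbrRatio,
              cardiacAmplitude = cardiacAmplitude, cardiacFreq = cardiacFreq,
              respAmplitude = respAmplitude, respFreq = respFreq,
              mayerAmplitude = mayerAmplitude, mayerFreq = mayerFreq,
              driftSd = driftSd, whiteSd = whiteSd, hrf = hrf,
              seed = as.integer(seed))
  if (cfg$nChannels < 1L) stop("'nChannels' must be positive")
  if (!is.null(activeChannels)) {
    if (any(activeChannels < 1L | activeChannels > cfg$nChannels))
      stop("'activeChannels' must lie in [1, nChannels]")
    cfg$activeChannels <- as.integer(sort(unique(activeChannels)))
  }
  amps <- c(cardiacAmplitude, respAmplitude, mayerAmplitude, driftSd,
            whiteSd, activationAmplitude)
  if (any(amps < 0)) stop("amplitudes must be non-negative")
  if (length(restRange) != 2L || diff(restRange) < 0 || restRange[1L] < 0)
    stop("'restRange' must be c(min, max) with 0 <= min <= max")
  class(cfg) <- "fnirsSimConfig"
  cfg
}

# Rest draws come first off the seeded stream so that makeParadigm() and
# simulateRecording() agree on the schedule for the same config.
.paradigmFromRests <- function(cfg, rests) {
  t <- cfg$leadIn
  onset <- numeric(cfg$nTrials)
  for (j in seq_len(cfg$nTrials)) {
    onset[j] <- t + cfg$cueDuration
    t <- t + cfg$cueDuration + cfg$taskDuration + rests[j]
  }
  list(events = eventSchedule(onset, cfg$taskDuration, "task"),
       totalDuration = t + cfg$leadOut)
}

#' Build the task paradigm of a simulated session
#'
#' First task onset is \code{leadIn + cueDuration} (62 s with the defaults);
#' inter-trial rests are drawn uniformly from \code{restRange} using the
#' seeded stream, so the same config always yields the same schedule.
#'
#' @param cfg a configuration from [simConfig()].
#' @return An [EventSchedule-class] with \code{nTrials} task events.
#' @export
makeParadigm <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "fnirsSimConfig"))
  set.seed(cfg$seed)
  rests <- stats::runif(cfg$nTrials, cfg$restRange[1L], cfg$restRange[2L])
  .paradigmFromRests(cfg, rests)$events
}

.channelNoise <- function(cfg, t) {
  phases <- stats::runif(3L, 0, 2 * pi)
  n <- length(t)
  cfg$cardiacAmplitude * sin(2 * pi * cfg$cardiacFreq * t + phases[1L]) +
    cfg$respAmplitude  * sin(2 * pi * cfg$respFreq  * t + phases[2L]) +
    cfg$mayerAmplitude * sin(2 * pi * cfg$mayerFreq * t + phases[3L]) +
    cumsum(stats::rnorm(n, 0, cfg$driftSd)) +
    stats::rnorm(n, 0, cfg$whiteSd)
}

#' Simulate a synthetic fNIRS session with known active channels
#'
#' Generates \eqn{\Delta}HbO and \eqn{\Delta}HbR recordings: active channel
#' \eqn{i} carries
#' \eqn{\Delta HbO_i(t) = a_i \,(s \otimes h_c)(t) + \mathrm{noise}_i(t)},
#' inactive channels carry noise only;
#' \eqn{\Delta HbR = -\mathrm{ratio} \cdot \mathrm{activation} +}
#' independent noise.  All randomness (rest jitter, active-channel draw,
#' sinusoid phases, drift, white noise) comes from the single seeded stream,
#' so identical configs give bit-identical output.
#'
#' @param cfg a configuration from [simConfig()].
#' @param absorbance if TRUE, also return the raw dual-wavelength absorbance
#'   obtained through [inverseMbll()] with default MBLL parameters, for
#'   end-to-end testing of the conversion path.
#' @return A list with \code{hbo}, \code{hbr} ([NirsRecording-class]),
#'   \code{truth} ([SimTruth-class]) and, when requested,
#'   \code{absorbance}.
#' @examples
#' sim <- simulateRecording(simConfig(nChannels = 6, nTrials = 3, seed = 7))
#' activeChannels(sim$truth)
#' @export
simulateRecording <- function(cfg = simConfig(), absorbance = FALSE) {
  stopifnot(inherits(cfg, "fnirsSimConfig"))
  set.seed(cfg$seed)
  rests <- stats::runif(cfg$nTrials, cfg$restRange[1L], cfg$restRange[2L])
  par <- .paradigmFromRests(cfg, rests)
  active <- cfg$activeChannels
  if (is.null(active))
    active <- sort(sample.int(cfg$nChannels, min(cfg$nActive, cfg$nChannels)))
  n <- as.integer(round(par$totalDuration * cfg$fs))
  t <- (seq_len(n) - 1) / cfg$fs
  s <- boxcar(par$events, cfg$fs, n)
  hc <- canonicalHrf(cfg$hrf, cfg$fs, 32)
  response <- desiredHrf(hc, s)
  mask <- seq_len(cfg$nChannels) %in% active
  amps <- ifelse(mask, cfg$activationAmplitude, 0)
  hbo <- matrix(0, n, cfg$nChannels)
  hbr <- matrix(0, n, cfg$nChannels)
  for (i in seq_len(cfg$nChannels))
    hbo[, i] <- amps[i] * response + .channelNoise(cfg, t)
  for (i in seq_len(cfg$nChannels))
    hbr[, i] <- -cfg$hbrRatio * amps[i] * response + .channelNoise(cfg, t)
  ids <- paste0("ch", seq_len(cfg$nChannels))
  hboRec <- NirsRecording(hbo, fs = cfg$fs, chromophore = "HbO",
                          channelIds = ids)
  hbrRec <- NirsRecording(hbr, fs = cfg$fs, chromophore = "HbR",
                          channelIds = ids)
  truth <- new("SimTruth", activeMask = mask, amplitudes = amps,
               events = par$events, seed = as.numeric(cfg$seed),
               config = unclass(cfg))
  out <- list(hbo = hboRec, hbr = hbrRec, truth = truth)
  if (absorbance)
    out$absorbance <- inverseMbll(hboRec, hbrRec)
  out
}

#' Write simulator ground truth as JSON
#'
#' @param truth a [SimTruth-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSimTruth <- function(truth, path) {
  stopifnot(is(truth, "SimTruth"))
  doc <- list(seed = truth@seed,
              active_channels = which(truth@activeMask),
              amplitudes = truth@amplitudes,
              events = data.frame(onset = onsets(truth@events),
                                  duration = durations(truth@events),
                                  label = trialLabels(truth@events)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
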
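# Canonical two-gamma hemodynamic response function, task boxcar, and the
# desired hemodynamic response (dHRF) used as template and regressor.

#' Two-gamma HRF parameters
#'
#' The canonical impulse response is a difference of two gamma densities,
#' \deqn{h_c(t) = A\left[\frac{t^{\alpha_1-1}\beta_1^{\alpha_1}
#'   e^{-\beta_1 t}}{\Gamma(\alpha_1)} -
#'   c\,\frac{t^{\alpha_2-1}\beta_2^{\alpha_2}
#'   e^{-\beta_2 t}}{\Gamma(\alpha_2)}\right],}
#' with time in seconds.  The defaults are the widespread canonical
#' convention: peak delay 6, undershoot delay 16, unit dispersions,
#' peak-to-undershoot ratio 1/6, unit amplitude, which places the response
#' peak near 5 s.
#'
#' @param A amplitude scale.
#' @param alpha1,beta1 shape/rate of the peak gamma (\code{alpha1 > 1}).
#' @param alpha2,beta2 shape/rate of the undershoot gamma (\code{alpha2 > 1}).
#' @param c peak-to-undershoot ratio, \code{c >= 0}.
#' @return A validated parameter list.
#' @export
hrfParams <- function(A = 1, alpha1 = 6, beta1 = 1, alpha2 = 16, beta2 = 1,
                      c = 1 / 6) {
  if (alpha1 <= 1 || alpha2 <= 1)
    stop("'alpha1' and 'alpha2' must exceed 1")
  if (beta1 <= 0 || beta2 <= 0) stop("dispersions must be positive")
  if (c < 0) stop("'c' must be non-negative")
  list(A = A, alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
       beta2 = beta2, c = c)
}

#' Canonical two-gamma HRF sampled on a time grid
#'
#' @param params parameters from [hrfParams()].
#' @param fs sampling frequency (Hz).
#' @param duration kernel duration in seconds (default 32 s, after which the
#'   canonical response has decayed to negligible amplitude).
#' @return Numeric vector of \code{round(duration * fs)} samples, evaluated
#'   at \code{t = 0, 1/fs, 2/fs, ...} seconds; \code{h_c(0) = 0} since both
#'   shapes exceed 1.
#' @examples
#' h <- canonicalHrf(fs = 12.5)
#' (which.max(h) - 1) / 12.5   # peak near 5 s
#' @export
canonicalHrf <- function(params = hrfParams(), fs, duration = 32) {
  n <- as.integer(round(duration * fs))
  if (n < 2L) stop("kernel must span at least 2 samples")
  t <- (seq_len(n) - 1) / fs
  # each gamma term is exactly the gamma density in shape/rate form
  params$A * (stats::dgamma(t, shape = params$alpha1, rate = params$beta1) -
              params$c *
              stats::dgamma(t, shape = params$alpha2, rate = params$beta2))
}

#' Task boxcar function
#'
#' Binary task indicator on the sampling grid: 1 where sample time
#' \code{i/fs} falls in a half-open task interval
#' \code{[onset, onset + duration)}, 0 elsewhere.
#'
#' @param events an [EventSchedule-class].
#' @param fs sampling frequency (Hz).
#' @param nSamples output length in samples.
#' @return Numeric 0/1 vector of length \code{nSamples}.
#' @export
boxcar <- function(events, fs, nSamples) {
  stopifnot(is(events, "EventSchedule"))
  s <- numeric(nSamples)
  t <- (seq_len(nSamples) - 1) / fs
  for (j in seq_len(nTrials(events))) {
    on <- onsets(events)[j]
    s[t >= on & t < on + durations(events)[j]] <- 1
  }
  s
}

#' Desired hemodynamic response (dHRF)
#'
#' Truncated discrete convolution of the canonical HRF with the task boxcar:
#' with 0-based indices,
#' \code{h_M[k] = sum_{n=0}^{k} h_c[n] * s[k - n]}, truncated to the length
#' of \code{s}.  This is the template matched against measured responses and
#' the regressor of the t-value method.
#'
#' @param hc canonical HRF samples (see [canonicalHrf()]).
#' @param s boxcar samples (see [boxcar()]).
#' @return Numeric vector of \code{length(s)}.
#' @export
desiredHrf <- function(hc, s) {
  if (!length(hc) || !length(s)) stop("both vectors must be non-empty")
  # convolve(type = "open") reverses its second argument, so rev(s) gives
  # the true convolution; FFT round-off can leave ~1e-15 noise on exact
  # zeros, which is harmless downstream
  full <- stats::convolve(hc, rev(s), type = "open")
  full[seq_along(s)]
}

#' dHRF template for a single analysis epoch
#'
#' Builds the desired response for one trial as seen inside an epoch window:
#' a boxcar that is 1 during the task period (starting at offset 0 within the
#' window) convolved with the canonical HRF.  This is the template that
#' [zScoreSelect()] and [tValueSelect()] compare against the trial-averaged
#' response.
#'
#' @param fs sampling frequency (Hz).
#' @param taskDuration task period length in seconds (default 10 s).
#' @param window epoch window \code{c(start, end)} in seconds relative to
#'   task onset (default \code{c(0, 24)}, 300 samples at 12.5 Hz).
#' @param params HRF parameters from [hrfParams()].
#' @param kernelDuration canonical-HRF kernel length in seconds.
#' @return Numeric vector of \code{round(diff(window) * fs)} samples.
#' @export
epochTemplate <- function(fs, taskDuration = 10, window = c(0, 24),
                          params = hrfParams(), kernelDuration = 32) {
  n <- as.integer(round(diff(window) * fs))
  t <- window[1L] + (seq_len(n) - 1) / fs
  s <- as.numeric(t >= 0 & t < taskDuration)
  desiredHrf(canonicalHrf(params, fs, kernelDuration), s)
}
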
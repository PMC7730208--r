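# The three channel-selection methods: z-score of maximum cross-correlation
# (the proposed method), robust-GLM t-statistic, and baseline correction.

#' Maximum of the raw cross-correlation over all lags
#'
#' Computes the unnormalized cross-correlation
#' \deqn{r_{xy}(\tau) = \sum_t x(t)\, y(t - \tau)}
#' over every lag with any overlap (\eqn{\tau \in [-(n_y-1), n_x-1]}, full
#' zero-padded overlap) and returns its signed maximum and the lag at which
#' it occurs.  The raw (not unit-energy) sum is used deliberately: a
#' channel's response amplitude contributes to its score.  Anti-correlated
#' signals yield a low signed maximum rather than a high absolute one.
#'
#' Ties on the maximum are broken toward the smallest \code{abs(lag)}, then
#' toward the negative lag.
#'
#' @param x measured signal (numeric, length >= 2).
#' @param template template signal \eqn{y} (numeric, length >= 2).
#' @param normalized if TRUE, divide by the signal energies
#'   (\eqn{\sqrt{\sum x^2 \sum y^2}}) so the score is a correlation
#'   coefficient in [-1, 1]; off by default.
#' @return A list with \code{r} (the maximum) and \code{lag} (in samples;
#'   positive lag means \code{x} lags the template).
#' @examples
#' crossCorrelateMax(c(1, 2, 3), c(0, 0, 1))   # r = 3 at lag -2
#' @export
crossCorrelateMax <- function(x, template, normalized = FALSE) {
  nx <- length(x); ny <- length(template)
  if (nx < 2L || ny < 2L) stop("both signals need at least 2 samples")
  if (all(x == 0) || all(template == 0))
    return(list(r = 0, lag = 0L))
  # full cross-correlation via FFT; convolve(type = "open") reverses its
  # second argument, so passing the template as-is yields r(m - ny) at index m
  r <- stats::convolve(x, template, type = "open")
  lags <- seq.int(1L - ny, nx - 1L)
  if (normalized) r <- r / sqrt(sum(x^2) * sum(template^2))
  # tolerance absorbs FFT round-off when breaking ties
  best <- which(r >= max(r) - 1e-9 * max(abs(r)))
  best <- best[order(abs(lags[best]), lags[best])][1L]
  list(r = r[best], lag = lags[best])
}

.newSelection <- function(method, scores, aux, selected, params, ids) {
  new("SelectionResult", method = method, scores = as.numeric(scores),
      aux = aux, selected = as.logical(selected), params = params,
      channelIds = as.character(ids))
}

#' z-score channel selection
#'
#' For each channel, the maximum raw cross-correlation \eqn{r_i} between the
#' trial-averaged response and the dHRF template is computed; the vector of
#' maxima is standardized across channels,
#' \eqn{z_i = (r_i - \bar r) / \sigma_r}, and a channel is selected iff its
#' z-score is strictly positive.  A positive z-score marks a channel whose
#' template match is stronger than the channel-population average, i.e. a
#' cortically active channel.
#'
#' Since the z-transform is monotone, the selected set equals
#' \eqn{\{i : r_i > \bar r\}} and does not depend on whether the population
#' or sample standard deviation is used; the population convention is the
#' default for the reported values.
#'
#' @param avgTrial time-by-channel matrix of the trial-averaged response
#'   (see [averageTrials()]); at least 2 channels.
#' @param template dHRF template vector (see [epochTemplate()]).
#' @param sigma \code{"population"} (divide by n) or \code{"sample"}
#'   (divide by n-1) standard deviation for the reported z-values.
#' @param normalized passed to [crossCorrelateMax()].
#' @return A [SelectionResult-class] with z-scores as primary scores and
#'   \code{r}, \code{lag} as auxiliaries.
#' @export
zScoreSelect <- function(avgTrial, template, sigma = c("population", "sample"),
                         normalized = FALSE) {
  sigma <- match.arg(sigma)
  avgTrial <- as.matrix(avgTrial)
  nc <- ncol(avgTrial)
  if (nc < 2L) stop("z-score selection needs at least 2 channels")
  cc <- lapply(seq_len(nc), function(i)
    crossCorrelateMax(avgTrial[, i], template, normalized = normalized))
  r <- vapply(cc, `[[`, numeric(1L), "r")
  lag <- vapply(cc, `[[`, numeric(1L), "lag")
  sdr <- stats::sd(r)
  if (!is.finite(sdr) || sdr == 0)
    stop("degenerate input: all channels have identical correlation maxima")
  denom <- if (sigma == "population") sdr * sqrt((nc - 1) / nc) else sdr
  z <- (r - mean(r)) / denom
  ids <- if (!is.null(colnames(avgTrial))) colnames(avgTrial)
         else paste0("ch", seq_len(nc))
  .newSelection("zscore", z, data.frame(r = r, lag = lag), z > 0,
                list(sigma = sigma, normalized = normalized), ids)
}

#' Robust linear fit of a measured response on the dHRF
#'
#' Iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685, residual scale = median absolute residual /
#' 0.6745 re-estimated each iteration, convergence when the largest
#' coefficient change is at most \code{tol}, at most \code{maxIter}
#' iterations) for the model
#' \deqn{y = \phi\, x + \psi\, 1 + \varepsilon,}
#' where the intercept \eqn{\psi} absorbs baseline drift.  The activation
#' statistic is \eqn{t = \phi / SE(\phi)} with the standard error taken from
#' the robust-weighted covariance
#' \eqn{\hat\sigma^2 (X^T W X)^{-1}},
#' \eqn{\hat\sigma^2 = \sum w_i e_i^2 / (k - 2)}; the p-value is the
#' one-tailed upper-tail probability of the t-distribution with \eqn{k - 1}
#' degrees of freedom (activation is a positive-coefficient hypothesis).
#'
#' Fits whose robust residual scale collapses to zero (an exact fit on the
#' supporting points) report \code{t = +Inf, p = 0} for positive \eqn{\phi}
#' (and \code{t = -Inf, p = 1} for negative), the analytically forced limit.
#'
#' @param y measured response vector (length k >= 3).
#' @param x regressor vector (the dHRF), same length, non-constant.
#' @param tuning bisquare tuning constant.
#' @param tol convergence tolerance on coefficient change.
#' @param maxIter maximum IRLS iterations (warning on non-convergence; the
#'   last iterate is returned).
#' @return A list with \code{phi}, \code{psi}, \code{sePhi}, \code{t},
#'   \code{p}, \code{iterations}, \code{converged}.
#' @export
irlsFit <- function(y, x, tuning = 4.685, tol = 1e-8, maxIter = 50L) {
  k <- length(y)
  if (length(x) != k) stop("'y' and 'x' must have equal length")
  if (k < 3L) stop("need at least 3 samples")
  if (stats::sd(x) == 0) stop("constant regressor: design is not estimable")
  X <- cbind(x = x, intercept = 1)
  b <- stats::lm.fit(X, y)$coefficients
  tiny <- 1e-10 * max(abs(y), 1)
  converged <- FALSE
  exact <- FALSE
  it <- 0L
  w <- rep(1, k)
  repeat {
    e <- y - X %*% b
    scale <- stats::median(abs(e)) / 0.6745
    if (scale < tiny) { exact <- TRUE; converged <- TRUE; break }
    u <- as.numeric(e) / (tuning * scale)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    fit <- stats::lm.wfit(X, y, w)
    bNew <- fit$coefficients
    it <- it + 1L
    if (max(abs(bNew - b)) <= tol) { b <- bNew; converged <- TRUE; break }
    b <- bNew
    if (it >= maxIter) break
  }
  if (!converged)
    warning("IRLS did not converge in ", maxIter,
            " iterations; returning last iterate")
  phi <- unname(b[1L]); psi <- unname(b[2L])
  if (exact) {
    se <- 0
    tval <- if (phi > 0) Inf else if (phi < 0) -Inf else 0
    p <- if (phi > 0) 0 else if (phi < 0) 1 else 0.5
  } else {
    e <- as.numeric(y - X %*% b)
    sigma2 <- sum(w * e^2) / (k - 2)
    xtwx <- crossprod(X, w * X)
    se <- sqrt(sigma2 * solve(xtwx)[1L, 1L])
    if (se == 0) {
      tval <- if (phi > 0) Inf else if (phi < 0) -Inf else 0
      p <- if (phi > 0) 0 else if (phi < 0) 1 else 0.5
    } else {
      tval <- phi / se
      p <- stats::pt(tval, df = k - 1, lower.tail = FALSE)
    }
  }
  list(phi = phi, psi = psi, sePhi = se, t = tval, p = p,
       iterations = it, converged = converged)
}

#' t-value channel selection (robust GLM)
#'
#' Fits each channel's trial-averaged response on the dHRF template with
#' [irlsFit()] and selects the channels whose activation t-statistic exceeds
#' the critical value with a significant one-tailed p-value:
#' \code{t > tCrt & p < pMax}.
#'
#' @param avgTrial time-by-channel matrix of trial-averaged responses.
#' @param template dHRF template, same length as the epoch.
#' @param tCrt critical t value; defaults to the upper one-tailed 0.05
#'   quantile at \code{k - 1} degrees of freedom (1.65 for the 300-sample
#'   epoch).
#' @param pMax significance threshold (default 0.05).
#' @param ... passed to [irlsFit()].
#' @return A [SelectionResult-class] with t-statistics as primary scores and
#'   \code{phi}, \code{psi}, \code{se}, \code{p} as auxiliaries.
#' @export
tValueSelect <- function(avgTrial, template, tCrt = NULL, pMax = 0.05, ...) {
  avgTrial <- as.matrix(avgTrial)
  k <- nrow(avgTrial)
  if (length(template) != k)
    stop("template length must equal the epoch length")
  if (is.null(tCrt)) tCrt <- tCritical(0.05, k - 1L)
  fits <- lapply(seq_len(ncol(avgTrial)), function(i)
    irlsFit(avgTrial[, i], template, ...))
  tv <- vapply(fits, `[[`, numeric(1L), "t")
  p <- vapply(fits, `[[`, numeric(1L), "p")
  aux <- data.frame(phi = vapply(fits, `[[`, numeric(1L), "phi"),
                    psi = vapply(fits, `[[`, numeric(1L), "psi"),
                    se = vapply(fits, `[[`, numeric(1L), "sePhi"),
                    p = p)
  ids <- if (!is.null(colnames(avgTrial))) colnames(avgTrial)
         else paste0("ch", seq_len(ncol(avgTrial)))
  .newSelection("tvalue", tv, aux, tv > tCrt & p < pMax,
                list(tCrt = tCrt, pMax = pMax), ids)
}

#' Baseline-correction channel selection
#'
#' The simplest comparator: per channel, the peak of the averaged task-period
#' response is compared with the peak of the averaged rest-period response;
#' a channel is selected iff its task peak strictly exceeds its rest peak.
#'
#' @param taskEp [EpochSet-class] of task-period epochs.
#' @param restEp [EpochSet-class] of rest-period epochs over the same
#'   channels.
#' @return A [SelectionResult-class] with the task-minus-rest peak
#'   difference as primary score and both peaks as auxiliaries.
#' @export
baselineSelect <- function(taskEp, restEp) {
  stopifnot(is(taskEp, "EpochSet"), is(restEp, "EpochSet"))
  if (!identical(channelIds(taskEp), channelIds(restEp)))
    stop("task and rest epoch sets must cover the same channels")
  if (nTrials(taskEp) == 0L || nTrials(restEp) == 0L)
    stop("both epoch sets must be non-empty")
  taskPeak <- apply(averageTrials(taskEp), 2L, max)
  restPeak <- apply(averageTrials(restEp), 2L, max)
  .newSelection("baseline", taskPeak - restPeak,
                data.frame(taskPeak = taskPeak, restPeak = restPeak),
                taskPeak > restPeak, list(), channelIds(taskEp))
}

.checkSelection <- function(n, selection) {
  if (nChannels(selection) != n)
    stop("selection channel count (", nChannels(selection),
         ") does not match the input (", n, ")")
  keep <- which(selection@selected)
  if (!length(keep))
    stop("empty selection: no channels were selected")
  keep
}

#' @describeIn applySelection subset a recording's channels.
#' @export
setMethod("applySelection", "NirsRecording", function(x, selection = NULL) {
  if (is.null(selection)) return(x)
  keep <- .checkSelection(nChannels(x), selection)
  mont <- if (is.null(montage(x))) NULL else montage(x)[keep, , drop = FALSE]
  NirsRecording(signalMatrix(x)[, keep, drop = FALSE], fs = fs(x),
                chromophore = chromophore(x),
                channelIds = channelIds(x)[keep], montage = mont)
})

#' @describeIn applySelection subset an epoch set's channels.
#' @export
setMethod("applySelection", "EpochSet", function(x, selection = NULL) {
  if (is.null(selection)) return(x)
  keep <- .checkSelection(nChannels(x), selection)
  new("EpochSet", epochs = x@epochs[, , keep, drop = FALSE],
      window = x@window, fs = x@fs, trialLabels = x@trialLabels,
      channelIds = x@channelIds[keep])
})
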
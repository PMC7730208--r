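# Spatio-temporal feature extraction and min-max normalization.

.FEATURES <- c("mean", "peak", "slope", "variance", "skewness", "kurtosis")
.MOMENT_FEATURES <- c("variance", "skewness", "kurtosis")

.slopePerSecond <- function(v, fs) {
  t <- (seq_along(v) - 1) / fs
  tc <- t - mean(t)
  sum(tc * (v - mean(v))) / sum(tc^2)
}

.featureFun <- function(name, fs) {
  switch(name,
    mean = function(v) mean(v),
    peak = function(v) max(v),
    slope = function(v) .slopePerSecond(v, fs),
    variance = function(v) stats::var(v),
    skewness = function(v) e1071::skewness(v, type = 1),
    kurtosis = function(v) e1071::kurtosis(v, type = 1),
    stop("unknown feature: ", name))
}

#' Extract spatio-temporal features for one class
#'
#' Two-step spatio-temporal aggregation: per trial, the selected channels are
#' averaged spatially, then each statistic is computed over the epoch window
#' temporally.  \code{slope} is the least-squares line coefficient in signal
#' units per second (so it does not depend on the sampling rate);
#' \code{variance}, \code{skewness} and \code{kurtosis} are standard sample
#' moments (kurtosis as excess).
#'
#' @param ep an [EpochSet-class] (typically the task-period window
#'   \code{c(0, 10)} s or a rest window of the same length).
#' @param selection a [SelectionResult-class] restricting the channels, or
#'   \code{NULL} to use all channels.
#' @param features character vector from \code{"mean"}, \code{"peak"},
#'   \code{"slope"}, \code{"variance"}, \code{"skewness"}, \code{"kurtosis"};
#'   default the three-feature set mean/peak/slope.
#' @return An (unlabeled, unnormalized) [FeatureMatrix-class] with one row
#'   per trial.
#' @export
extractFeatures <- function(ep, selection = NULL,
                            features = c("mean", "peak", "slope")) {
  stopifnot(is(ep, "EpochSet"))
  features <- match.arg(features, .FEATURES, several.ok = TRUE)
  if (nTrials(ep) == 0L) stop("no epochs to extract features from")
  ep <- applySelection(ep, selection)
  if (nSamples(ep) < 3L && any(features %in% .MOMENT_FEATURES))
    stop("moment features need at least 3 samples per epoch")
  funs <- lapply(features, .featureFun, fs = fs(ep))
  vals <- t(vapply(seq_len(nTrials(ep)), function(j) {
    m <- ep@epochs[j, , , drop = FALSE]
    dim(m) <- dim(m)[2:3]          # time x channel
    v <- rowMeans(m)               # spatial average over selected channels
    vapply(funs, function(f) f(v), numeric(1L))
  }, numeric(length(features))))
  if (length(features) == 1L) vals <- matrix(vals, ncol = 1L)
  colnames(vals) <- features
  new("FeatureMatrix", values = vals,
      classLabels = rep("", nrow(vals)), normalized = FALSE)
}

#' Min-max feature normalization
#'
#' Rescales every feature column over all rows (both classes jointly) to
#' \eqn{Y' = (Y - \min Y) / (\max Y - \min Y) \in [0, 1]}.  A constant column
#' maps to all zeros (0/0 guarded).
#'
#' @param fm a [FeatureMatrix-class] with at least 2 rows.
#' @return The normalized [FeatureMatrix-class].
#' @export
minmaxNormalize <- function(fm) {
  stopifnot(is(fm, "FeatureMatrix"))
  v <- fm@values
  if (nrow(v) < 2L) stop("normalization needs at least 2 rows")
  out <- apply(v, 2L, function(col) {
    rng <- max(col) - min(col)
    if (rng == 0) rep(0, length(col)) else (col - min(col)) / rng
  })
  colnames(out) <- colnames(v)
  initialize(fm, values = out, normalized = TRUE)
}

#' Build the labeled, normalized task-vs-rest feature matrix
#'
#' Stacks the task-class rows on the rest-class rows, labels them and applies
#' [minmaxNormalize()] jointly over both classes, producing the
#' \code{2n x f} matrix the classifier consumes (with the default 20 trials
#' and 3 features: a 20 x 3 block per class).
#'
#' @param taskEp task-window [EpochSet-class].
#' @param restEp rest-window [EpochSet-class] (same channels; a warning is
#'   issued if trial counts are unbalanced).
#' @param selection a [SelectionResult-class] or \code{NULL} for all
#'   channels.
#' @param features feature names as in [extractFeatures()].
#' @return A labeled, normalized [FeatureMatrix-class].
#' @export
buildFeatureMatrix <- function(taskEp, restEp, selection = NULL,
                               features = c("mean", "peak", "slope")) {
  if (nTrials(taskEp) != nTrials(restEp))
    warning("unbalanced trial counts: ", nTrials(taskEp), " task vs ",
            nTrials(restEp), " rest")
  taskFm <- extractFeatures(taskEp, selection, features)
  restFm <- extractFeatures(restEp, selection, features)
  fm <- new("FeatureMatrix",
            values = rbind(taskFm@values, restFm@values),
            classLabels = c(rep("task", nrow(taskFm@values)),
                            rep("rest", nrow(restFm@values))),
            normalized = FALSE)
  minmaxNormalize(fm)
}

#' Export a feature matrix as CSV
#'
#' Writes the feature columns plus a \code{class} label column.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureMatrix <- function(fm, path) {
  stopifnot(is(fm, "FeatureMatrix"))
  tab <- data.frame(fm@values, class = fm@classLabels, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
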
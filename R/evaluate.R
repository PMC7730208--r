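# Statistical comparison of selection methods, critical values, activation
# maps and ground-truth selection metrics.

#' Two-tailed paired Student's t-test
#'
#' Paired differences \eqn{d = a - b},
#' \eqn{t = \bar d / (s_d / \sqrt n)} with the sample (n-1) standard
#' deviation, two-tailed p from the t-distribution with \eqn{n - 1} degrees
#' of freedom.  Constant differences (including \code{a == b}) have zero
#' variance and raise a degenerate-input error.
#'
#' @param a,b paired numeric vectors of equal length (n >= 2), e.g.
#'   per-subject accuracies of two methods.
#' @return A list with \code{t} and \code{p}.
#' @examples
#' pairedTTest(c(2, 4, 6), c(1, 2, 3))   # t = 3.46, p = 0.074
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  if (stats::sd(a - b) == 0)
    stop("degenerate input: paired differences have zero variance")
  res <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(res$statistic), p = res$p.value)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param familyAlpha family-wise alpha in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return \code{familyAlpha / m}, rounded to 4 decimals for reporting
#'   (0.05 over 3 comparisons gives the 0.0167 threshold).
#' @export
bonferroniAlpha <- function(familyAlpha = 0.05, m = 3L) {
  if (familyAlpha <= 0 || familyAlpha >= 1)
    stop("'familyAlpha' must be in (0, 1)")
  if (m < 1L) stop("'m' must be at least 1")
  round(familyAlpha / m, 4L)
}

#' One-tailed Student-t critical value
#'
#' Upper one-tailed quantile \eqn{t_{crt}} of the t-distribution; at
#' \code{alpha = 0.05} and 299 degrees of freedom (a 300-sample epoch) it
#' rounds to 1.65, the threshold of the t-value selection rule.
#'
#' @param alpha one-tailed significance level in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @return The critical value at full precision (round for reporting).
#' @export
tCritical <- function(alpha = 0.05, df) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (df < 1L) stop("'df' must be at least 1")
  stats::qt(1 - alpha, df = df)
}

#' Per-channel activation table
#'
#' Min-max normalizes a selection result's score vector to [0, 1] (constant
#' scores map to all zeros) and tabulates it per channel, with montage
#' coordinates when available, in channel order.  This is the tabular form
#' of an activation map; see [plotActivationMap()] for the optional scatter
#' rendering.
#'
#' @param result a [SelectionResult-class].
#' @param montage optional data.frame with \code{x}, \code{y} rows matching
#'   the channels.
#' @return A data.frame with columns \code{channel}, \code{score},
#'   \code{normalizedScore}, \code{selected} and, if a montage was given,
#'   \code{x}, \code{y}.
#' @export
activationMap <- function(result, montage = NULL) {
  stopifnot(is(result, "SelectionResult"))
  s <- result@scores
  rng <- max(s) - min(s)
  norm <- if (rng == 0) rep(0, length(s)) else (s - min(s)) / rng
  out <- data.frame(channel = result@channelIds, score = s,
                    normalizedScore = norm, selected = result@selected)
  if (!is.null(montage)) {
    if (nrow(montage) != length(s))
      stop("montage rows must match the channel count")
    out$x <- montage$x
    out$y <- montage$y
  }
  out
}

#' Scatter rendering of an activation table
#'
#' @param map output of [activationMap()] including montage coordinates.
#' @param ... passed to [graphics::plot()].
#' @return The map, invisibly.
#' @export
plotActivationMap <- function(map, ...) {
  if (is.null(map$x) || is.null(map$y))
    stop("montage coordinates required for plotting")
  pal <- grDevices::hcl.colors(100, "YlOrRd", rev = TRUE)
  cols <- pal[pmax(1L, ceiling(map$normalizedScore * 100))]
  graphics::plot(map$x, map$y, pch = 21, bg = cols, cex = 2,
                 xlab = "x", ylab = "y", ...)
  graphics::text(map$x, map$y, map$channel, pos = 3, cex = 0.6)
  invisible(map)
}

#' Selection sensitivity and specificity against simulator ground truth
#'
#' @param result a [SelectionResult-class].
#' @param truth a [SimTruth-class] with matching channel count.
#' @return A list with \code{sensitivity} (TP / (TP + FN); \code{NaN} with a
#'   warning when there are no truly active channels) and \code{specificity}
#'   (TN / (TN + FP)).
#' @export
selectionMetrics <- function(result, truth) {
  stopifnot(is(result, "SelectionResult"), is(truth, "SimTruth"))
  act <- truth@activeMask
  if (length(act) != nChannels(result))
    stop("truth and result channel counts differ")
  sel <- result@selected
  tp <- sum(sel & act); fn <- sum(!sel & act)
  tn <- sum(!sel & !act); fp <- sum(sel & !act)
  sens <- if (tp + fn == 0L) {
    warning("no truly active channels: sensitivity undefined")
    NaN
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0L) NaN else tn / (tn + fp)
  list(sensitivity = sens, specificity = spec)
}

#' Compare selection methods on per-subject accuracies
#'
#' Summarizes per-subject accuracies by task and method and tests a
#' reference method against each comparator with the two-tailed paired test,
#' at a Bonferroni-adjusted threshold.
#'
#' @param acc long-format data.frame with columns \code{subject},
#'   \code{task}, \code{method}, \code{accuracy} (percent), e.g. from
#'   [benchmarkAccuracies()].
#' @param reference method name tested against the others.
#' @param comparators method names to compare the reference with; default
#'   all other methods present.
#' @param familyAlpha family-wise alpha.
#' @param m number of comparisons for the Bonferroni adjustment (default 3,
#'   matching the reported 0.0167 threshold).
#' @return An [EvalReport-class].
#' @export
evaluateAccuracies <- function(acc, reference = "zscore",
                               comparators = NULL, familyAlpha = 0.05,
                               m = 3L) {
  need <- c("subject", "task", "method", "accuracy")
  if (!all(need %in% names(acc)))
    stop("'acc' must have columns: ", paste(need, collapse = ", "))
  if (is.null(comparators))
    comparators <- setdiff(unique(acc$method), reference)
  summ <- do.call(rbind, lapply(split(acc, acc[c("task", "method")]),
    function(g) data.frame(task = g$task[1L], method = g$method[1L],
                           mean = round(mean(g$accuracy), 1L),
                           sd = round(stats::sd(g$accuracy), 1L),
                           n = nrow(g))))
  rownames(summ) <- NULL
  comps <- list()
  for (task in unique(acc$task)) {
    sub <- acc[acc$task == task, ]
    ref <- sub[sub$method == reference, ]
    ref <- ref[order(ref$subject), ]
    for (cmp in comparators) {
      other <- sub[sub$method == cmp, ]
      other <- other[order(other$subject), ]
      tt <- pairedTTest(ref$accuracy, other$accuracy)
      comps[[length(comps) + 1L]] <-
        data.frame(task = task, method1 = reference, method2 = cmp,
                   t = tt$t, p = tt$p)
    }
  }
  new("EvalReport", accuracies = summ, comparisons = do.call(rbind, comps),
      adjustedAlpha = bonferroniAlpha(familyAlpha, m))
}
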
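# Fisher linear discriminant analysis and leave-one-trial-out
# cross-validation.

.classSplit <- function(fm) {
  labs <- classLabels(fm)
  classes <- unique(labs)
  if (length(classes) != 2L)
    stop("exactly 2 classes required, got: ",
         paste(classes, collapse = ", "))
  list(classes = classes,
       idx = lapply(classes, function(cl) which(labs == cl)))
}

#' Fit a two-class Fisher discriminant
#'
#' Maximizes Fisher's criterion \eqn{J(X) = X^T S_B X / X^T S_W X}, where
#' \eqn{S_W} is the pooled within-class scatter and \eqn{S_B} the
#' between-class scatter.  For two classes the leading generalized
#' eigenvector is, up to scale, \eqn{S_W^{-1} (\mu_1 - \mu_2)}, which is the
#' closed form used here.  The decision threshold is the midpoint of the
#' projected class means (equal priors).
#'
#' A singular within-class scatter (e.g. perfectly separable synthetic
#' features) is ridge-regularized once with
#' \eqn{\lambda\, \mathrm{tr}(S_W)/d \cdot I}, \eqn{\lambda = 10^{-6}},
#' before refusing.
#'
#' @param fm a labeled [FeatureMatrix-class] with exactly two classes, each
#'   non-empty (single-sample classes fall back to the ridge path).
#' @return An [LDAModel-class].
#' @export
ldaFit <- function(fm) {
  stopifnot(is(fm, "FeatureMatrix"))
  sp <- .classSplit(fm)
  v <- featureValues(fm)
  d <- ncol(v)
  # single-sample classes are tolerated (they arise in tiny cross-validation
  # folds); their within-class scatter is zero and the ridge fallback applies
  if (any(lengths(sp$idx) < 1L)) stop("every class needs at least 1 sample")
  mu <- do.call(rbind, lapply(sp$idx,
                              function(ix) colMeans(v[ix, , drop = FALSE])))
  Sw <- matrix(0, d, d)
  for (g in 1:2) {
    cent <- sweep(v[sp$idx[[g]], , drop = FALSE], 2L, mu[g, ])
    Sw <- Sw + crossprod(cent)
  }
  delta <- mu[1L, ] - mu[2L, ]
  w <- tryCatch(solve(Sw, delta), error = function(e) NULL)
  if (is.null(w) || !all(is.finite(w))) {
    tr <- sum(diag(Sw))
    ridge <- if (tr > 0) 1e-6 * tr / d else 1e-6
    w <- solve(Sw + diag(ridge, d), delta)
  }
  pm <- as.numeric(mu %*% w)
  new("LDAModel", projection = as.numeric(w), classMeans = mu,
      classes = sp$classes, threshold = mean(pm), projectedMeans = pm)
}

#' Classify feature rows with a fitted discriminant
#'
#' Projects the rows on the discriminant axis and labels each by the side of
#' the midpoint threshold; values exactly at the threshold go to the first
#' class (deterministic tie rule).
#'
#' @param model an [LDAModel-class].
#' @param rows numeric matrix (or single vector) of feature rows matching
#'   the model's dimension.
#' @return Character vector of class labels.
#' @export
ldaPredict <- function(model, rows) {
  stopifnot(is(model, "LDAModel"))
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1L)
  if (ncol(rows) != length(model@projection))
    stop("feature dimension (", ncol(rows), ") does not match the model (",
         length(model@projection), ")")
  proj <- as.numeric(rows %*% model@projection)
  orient <- sign(model@projectedMeans[1L] - model@projectedMeans[2L])
  side <- orient * (proj - model@threshold)
  ifelse(side >= 0, model@classes[1L], model@classes[2L])
}

#' Leave-one-trial-out cross-validated accuracy
#'
#' With \eqn{n} trials per class, fold \eqn{j} holds out trial \eqn{j}'s task
#' row together with its paired rest row, trains the discriminant on the
#' remaining \eqn{2(n-1)} rows and classifies the two held-out rows;
#' repeated \eqn{n} times.  Accuracy is \code{correct / (2n) * 100},
#' reported to one decimal place.
#'
#' Rows are paired by order of appearance within each class, so a feature
#' matrix from [buildFeatureMatrix()] pairs trial \eqn{j} of the task block
#' with trial \eqn{j} of the rest block.
#'
#' @param fm a labeled, two-class, balanced [FeatureMatrix-class].
#' @return A list with \code{accuracy} (percent, 1 decimal) and
#'   \code{folds}, a data.frame with one row per held-out observation
#'   (\code{fold}, \code{row}, \code{truth}, \code{predicted},
#'   \code{correct}).
#' @export
loocvAccuracy <- function(fm) {
  stopifnot(is(fm, "FeatureMatrix"))
  sp <- .classSplit(fm)
  n1 <- length(sp$idx[[1L]]); n2 <- length(sp$idx[[2L]])
  if (n1 != n2)
    stop("unbalanced classes (", n1, " vs ", n2, "): trial pairing undefined")
  v <- featureValues(fm)
  labs <- classLabels(fm)
  folds <- vector("list", n1)
  for (j in seq_len(n1)) {
    hold <- c(sp$idx[[1L]][j], sp$idx[[2L]][j])
    trainFm <- new("FeatureMatrix", values = v[-hold, , drop = FALSE],
                   classLabels = labs[-hold], normalized = fm@normalized)
    model <- ldaFit(trainFm)
    pred <- ldaPredict(model, v[hold, , drop = FALSE])
    folds[[j]] <- data.frame(fold = j, row = hold, truth = labs[hold],
                             predicted = pred, correct = pred == labs[hold])
  }
  folds <- do.call(rbind, folds)
  list(accuracy = round(100 * mean(folds$correct), 1L), folds = folds)
}
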
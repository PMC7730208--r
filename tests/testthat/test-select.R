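test_that("cross-correlation maximum matches the all-lag brute force", {
  expect_equal(crossCorrelateMax(c(1, 2, 3), c(0, 0, 1)),
               list(r = 3, lag = 0L))          # overlap x[3] * y[3]
  expect_equal(crossCorrelateMax(c(1, 2, 3), c(0, 0, 0)),
               list(r = 0, lag = 0L))          # zero template, tie rule

  set.seed(41)
  for (i in 1:40) {
    x <- rnorm(sample(2:128, 1)); y <- rnorm(sample(2:128, 1))
    got <- crossCorrelateMax(x, y)
    want <- bruteXcorrMax(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-9)
    expect_equal(got$lag, want$lag)
  }
  expect_error(crossCorrelateMax(1, c(1, 2)), "2 samples")
})

test_that("a delayed copy of the template is found at its lag", {
  tpl <- epochTemplate(fs = 12.5)
  delayed <- c(numeric(10), tpl)[seq_along(tpl)]
  expect_equal(crossCorrelateMax(delayed, tpl)$lag, 10L)
  expect_equal(bruteXcorrMax(delayed, tpl)$lag, 10L)
})

test_that("normalized cross-correlation is bounded by 1 and unit on self", {
  set.seed(42)
  x <- rnorm(64)
  self <- crossCorrelateMax(x, x, normalized = TRUE)
  expect_equal(self$r, 1, tolerance = 1e-9)
  expect_equal(self$lag, 0L)
  y <- rnorm(64)
  expect_lte(abs(crossCorrelateMax(x, y, normalized = TRUE)$r), 1 + 1e-12)
})

test_that("z-scores follow the closed form and select strictly positive ones", {
  # channels are scaled unit impulses, so r = (1, 2, 3) exactly
  avg <- cbind(a = c(0, 1, 0, 0), b = c(0, 2, 0, 0), c = c(0, 3, 0, 0))
  tpl <- c(0, 1, 0, 0)
  res <- zScoreSelect(avg, tpl)
  expect_equal(res@aux$r, c(1, 2, 3))
  expect_equal(channelScores(res),
               c(a = -1.224745, b = 0, c = 1.224745), tolerance = 1e-6)
  expect_equal(unname(isSelected(res)), c(FALSE, FALSE, TRUE))  # z = 0 fails z > 0

  same <- cbind(avg[, 1], avg[, 1], avg[, 1])
  expect_error(zScoreSelect(same, tpl), "degenerate")
  expect_error(zScoreSelect(avg[, 1, drop = FALSE], tpl), "2 channels")
})

test_that("z-scores sum to zero and the selected set ignores the sigma convention", {
  set.seed(43)
  for (i in 1:25) {
    nc <- sample(3:12, 1)
    avg <- matrix(rnorm(40 * nc), 40, nc)
    tpl <- rnorm(40)
    pop <- zScoreSelect(avg, tpl, sigma = "population")
    sam <- zScoreSelect(avg, tpl, sigma = "sample")
    expect_lt(abs(sum(pop@scores)), 1e-9)
    expect_identical(pop@selected, sam@selected)
    expect_identical(pop@selected, pop@aux$r > mean(pop@aux$r))
    # at least one channel on each side when scores differ
    expect_gte(sum(pop@selected), 1L)
    expect_gte(sum(!pop@selected), 1L)
  }
})

test_that("robust fit recovers exact linear relations with the zero-SE convention", {
  x <- seq_len(300)
  f <- irlsFit(2 * x + 1, x)
  expect_equal(f$phi, 2, tolerance = 1e-10)
  expect_equal(f$psi, 1, tolerance = 1e-8)
  expect_identical(f$t, Inf)
  expect_identical(f$p, 0)

  fneg <- irlsFit(-x, x)
  expect_equal(fneg$phi, -1, tolerance = 1e-10)
  expect_lt(fneg$t, 0)
  expect_identical(fneg$p, 1)

  expect_error(irlsFit(rnorm(10), rep(1, 10)), "constant")
  expect_error(irlsFit(1:2, 1:2), "at least 3")
})

test_that("bisquare IRLS agrees with the reference robust fitter", {
  # the redescending estimator locks onto the 3 collinear points of this
  # classic 4-point set, as the reference implementation does
  f <- irlsFit(c(1, 2, 2, 4), c(0, 1, 2, 3))
  ref <- MASS::rlm(y ~ x, data.frame(x = c(0, 1, 2, 3), y = c(1, 2, 2, 4)),
                   psi = MASS::psi.bisquare, maxit = 100)
  expect_equal(f$phi, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(f$psi, unname(coef(ref)[1]), tolerance = 1e-6)
  expect_identical(f$t, Inf)

  set.seed(44)
  tpl <- epochTemplate(fs = 12.5)
  for (i in 1:5) {
    y <- 0.7 * tpl + 0.1 + rnorm(300, 0, 0.25)
    mine <- irlsFit(y, tpl)
    theirs <- MASS::rlm(y ~ x, data.frame(x = tpl, y = y),
                        psi = MASS::psi.bisquare, maxit = 100)
    expect_equal(mine$phi, unname(coef(theirs)[2]), tolerance = 1e-4)
  }
})

test_that("IRLS equals OLS when weights are uniform and resists gross outliers", {
  # residual pattern orthogonal to the design with equal magnitudes: the
  # bisquare weights are identical across points, so IRLS = OLS exactly
  x <- seq_len(300)
  y <- 1.5 + 0.01 * x + 0.2 * rep(c(1, -1, -1, 1), 75)
  f <- irlsFit(y, x)
  ols <- stats::lm.fit(cbind(x, 1), y)$coefficients
  expect_lt(abs(f$phi - ols[1]) / abs(ols[1]), 1e-6)
  expect_lt(abs(f$psi - ols[2]) / abs(ols[2]), 1e-6)

  # 5% gross outliers at high-leverage points bias the OLS slope; the
  # robust slope stays closer to the truth
  set.seed(45)
  for (i in 1:10) {
    x <- rnorm(200); y <- 1 + 2 * x + rnorm(200, 0, 0.2)
    bad <- order(x, decreasing = TRUE)[1:10]
    y[bad] <- y[bad] + 15
    robust <- irlsFit(y, x)$phi
    plain <- stats::lm.fit(cbind(x, 1), y)$coefficients[1]
    expect_lt(abs(robust - 2), abs(plain - 2))
  }
})

test_that("t-value selection accepts template-like channels and rejects inverted ones", {
  set.seed(46)
  tpl <- epochTemplate(fs = 12.5)
  avg <- cbind(pos = tpl + rnorm(300, 0, 0.05 * max(tpl)),
               neg = -tpl,
               noise = rnorm(300))
  res <- tValueSelect(avg, tpl)
  expect_true(isSelected(res)[["pos"]])
  expect_false(isSelected(res)[["neg"]])
  expect_lt(channelScores(res)[["neg"]], 0)
  expect_equal(res@params$tCrt, tCritical(0.05, 299))
  expect_error(tValueSelect(avg, tpl[1:100]), "length")
})

test_that("baseline selection compares task and rest peaks strictly", {
  mk <- function(peak) {
    a <- array(0, dim = c(3, 10, 2))
    a[, 5, 1] <- peak; a[, 5, 2] <- 1
    epochsFromArray(a)
  }
  res <- baselineSelect(mk(2), mk(1))
  expect_identical(unname(isSelected(res)), c(TRUE, FALSE))  # equal peaks lose
  expect_equal(res@aux$taskPeak, c(2, 1))
  inv <- baselineSelect(mk(0.5), mk(1))
  expect_identical(unname(isSelected(inv)), c(FALSE, FALSE))
})

test_that("applySelection subsets channels preserving order", {
  rec <- recFromMatrix(matrix(1:30, 10, 3))
  sel <- function(mask) new("SelectionResult", method = "zscore",
                            scores = as.numeric(mask), aux = data.frame(),
                            selected = mask, params = list(),
                            channelIds = channelIds(rec))
  expect_identical(signalMatrix(applySelection(rec, sel(c(TRUE, TRUE, TRUE)))),
                   signalMatrix(rec))
  sub <- applySelection(rec, sel(c(TRUE, FALSE, TRUE)))
  expect_identical(channelIds(sub), c("ch1", "ch3"))
  expect_identical(signalMatrix(sub), signalMatrix(rec)[, c(1, 3)])
  expect_error(applySelection(rec, sel(c(FALSE, FALSE, FALSE))), "empty")
  expect_identical(applySelection(rec, NULL), rec)  # all-channels arm
})
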
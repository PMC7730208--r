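constEpochs <- function(value, nTrial = 4, nTime = 125, nCh = 3) {
  epochsFromArray(array(value, dim = c(nTrial, nTime, nCh)))
}

test_that("features of simple signals take their closed-form values", {
  fm <- extractFeatures(constEpochs(0.7))
  expect_true(all(featureValues(fm)[, "mean"] == 0.7))
  expect_true(all(featureValues(fm)[, "peak"] == 0.7))
  expect_lt(max(abs(featureValues(fm)[, "slope"])), 1e-12)

  # line 2t + 1 sampled at 12.5 Hz has slope 2 per second
  t <- (0:124) / 12.5
  a <- array(rep(2 * t + 1, each = 2), dim = c(2, 125, 1))
  fm <- extractFeatures(epochsFromArray(a))
  expect_equal(unname(featureValues(fm)[, "slope"]), c(2, 2),
               tolerance = 1e-9)

  # symmetric signal has zero skewness
  sym <- sin(2 * pi * (0:124) / 125)
  fmS <- extractFeatures(epochsFromArray(array(sym, dim = c(1, 125, 1))),
                         features = c("mean", "skewness"))
  expect_lt(abs(featureValues(fmS)[, "skewness"]), 1e-9)
})

test_that("spatial average then statistic equals the statistic of the mean channel", {
  set.seed(51)
  a <- array(rnorm(5 * 60 * 4), dim = c(5, 60, 4))
  fm <- extractFeatures(epochsFromArray(a),
                        features = c("mean", "peak", "slope", "variance"))
  for (j in 1:5) {
    v <- rowMeans(a[j, , ])                   # brute-force spatial average
    expect_equal(featureValues(fm)[j, "mean"], mean(v), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(featureValues(fm)[j, "peak"], max(v), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(featureValues(fm)[j, "variance"], var(v), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("min-max normalization follows the rescaling rule", {
  fm <- fmFromValues(cbind(a = c(2, 4, 6), b = c(3, 3, 3), c = c(0, 0.5, 1)),
                     labels = rep("", 3))
  out <- featureValues(minmaxNormalize(fm))
  expect_equal(unname(out[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(out[, "b"]), c(0, 0, 0))    # constant column rule
  expect_equal(unname(out[, "c"]), c(0, 0.5, 1))  # already normalized
  expect_error(minmaxNormalize(fmFromValues(matrix(1, 1, 1), "")), "2 rows")
})

test_that("normalization is invariant to increasing affine transforms", {
  set.seed(52)
  raw <- matrix(rnorm(60), 20, 3)
  fm1 <- minmaxNormalize(fmFromValues(raw, rep("", 20)))
  fm2 <- minmaxNormalize(fmFromValues(3 * raw + 7, rep("", 20)))
  expect_equal(featureValues(fm1), featureValues(fm2), tolerance = 1e-12)
})

test_that("the task/rest matrix stacks, labels and normalizes jointly", {
  set.seed(53)
  task <- epochsFromArray(array(rnorm(20 * 125 * 3, mean = 1),
                                dim = c(20, 125, 3)))
  rest <- epochsFromArray(array(rnorm(20 * 125 * 3),
                                dim = c(20, 125, 3)))
  fm <- buildFeatureMatrix(task, rest)
  expect_equal(dim(featureValues(fm)), c(40L, 3L))   # 20 x 3 per class
  expect_identical(classLabels(fm), rep(c("task", "rest"), each = 20))
  expect_true(all(featureValues(fm) >= 0 & featureValues(fm) <= 1))
  expect_true(fm@normalized)

  fm6 <- buildFeatureMatrix(task, rest,
                            features = c("mean", "peak", "slope",
                                         "variance", "skewness", "kurtosis"))
  expect_equal(dim(featureValues(fm6)), c(40L, 6L))

  # identical classes give identical class means after normalization
  fmEq <- buildFeatureMatrix(task, task)
  v <- featureValues(fmEq)
  expect_equal(colMeans(v[1:20, , drop = FALSE]),
               colMeans(v[21:40, , drop = FALSE]), tolerance = 1e-12)

  short <- epochsFromArray(array(rnorm(10 * 125 * 3), dim = c(10, 125, 3)))
  expect_warning(buildFeatureMatrix(task, short), "unbalanced")
})

test_that("feature matrices export as labeled CSV", {
  fm <- fmFromValues(matrix(1:6, 3, 2), labels = c("task", "rest", "task"))
  path <- file.path(tempdir(), "features.csv")
  writeFeatureMatrix(fm, path)
  back <- read.csv(path)
  expect_equal(back$class, c("task", "rest", "task"))
  expect_equal(back$f1, 1:3)
})

test_that("degenerate feature requests are refused", {
  expect_error(extractFeatures(constEpochs(1, nTime = 2),
                               features = c("variance")), "3 samples")
  empty <- new("SelectionResult", method = "zscore", scores = c(0, 0, 0),
               aux = data.frame(), selected = rep(FALSE, 3), params = list(),
               channelIds = paste0("ch", 1:3))
  expect_error(extractFeatures(constEpochs(1), empty), "empty selection")
})
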
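sineRec <- function(freq, fsHz = 12.5, n = 3000) {
  t <- (0:(n - 1)) / fsHz
  recFromMatrix(matrix(sin(2 * pi * freq * t), ncol = 1), fsHz)
}

interiorAmp <- function(rec) {
  v <- signalMatrix(rec)[, 1]
  n <- length(v)
  max(abs(v[round(n / 6):round(5 * n / 6)]))
}

test_that("band-pass keeps in-band and rejects cardiac-band sinusoids", {
  expect_gt(interiorAmp(bandpassFilter(sineRec(0.09))), 0.9)
  expect_lt(interiorAmp(bandpassFilter(sineRec(0.09))), 1.1)
  expect_lt(interiorAmp(bandpassFilter(sineRec(1.1))), 0.01)
  # DC is stop-band
  dc <- bandpassFilter(recFromMatrix(matrix(1, 3000, 1)))
  expect_lt(interiorAmp(dc), 1e-6)
})

test_that("band-pass validates its band and the signal length", {
  expect_error(bandpassFilter(sineRec(0.09), low = 0.03, high = 7), "fs/2")
  expect_error(bandpassFilter(sineRec(0.09), low = 0.2, high = 0.1), "fs/2")
  short <- recFromMatrix(matrix(rnorm(20), 20, 1))
  expect_error(bandpassFilter(short), "short")
})

test_that("filtering and smoothing are channel-wise independent", {
  set.seed(21)
  m <- matrix(rnorm(3000 * 4), ncol = 4)
  perm <- c(3, 1, 4, 2)
  for (op in list(bandpassFilter, savgolSmooth)) {
    a <- signalMatrix(op(recFromMatrix(m)))
    b <- signalMatrix(op(recFromMatrix(m[, perm])))
    expect_equal(a[, perm], b, ignore_attr = TRUE)
  }
})

test_that("Savitzky-Golay reproduces low-degree polynomials and shrinks noise", {
  t <- (0:499) / 12.5
  poly <- recFromMatrix(matrix(2 + 0.5 * t - 0.1 * t^2 + 0.01 * t^3, ncol = 1))
  sm <- savgolSmooth(poly, windowSeconds = 1, polyorder = 3)
  interior <- 20:480
  expect_lt(max(abs(signalMatrix(sm)[interior, 1] -
                    signalMatrix(poly)[interior, 1])), 1e-9)

  set.seed(22)
  noise <- recFromMatrix(matrix(rnorm(2000), ncol = 1))
  expect_lt(var(signalMatrix(savgolSmooth(noise))[, 1]),
            var(signalMatrix(noise)[, 1]))

  # sub-sample window is the identity
  tinyWin <- savgolSmooth(noise, windowSeconds = 0.01)
  expect_identical(signalMatrix(tinyWin), signalMatrix(noise))
  expect_error(savgolSmooth(recFromMatrix(matrix(1:5, 5, 1)),
                            windowSeconds = 10), "longer")
})

test_that("epoching yields the expected sample counts and bounds errors", {
  rec <- recFromMatrix(matrix(rnorm(12000 * 3), ncol = 3))
  ev <- eventSchedule(62 + 27 * (0:19), 10, "task")
  ep <- epochTrials(rec, ev, c(0, 24))
  expect_equal(dim(epochArray(ep)), c(20L, 300L, 3L))  # 24 s x 12.5 Hz
  ep10 <- epochTrials(rec, ev, c(0, 10))
  expect_equal(nSamples(ep10), 125L)                   # 10 s x 12.5 Hz

  late <- eventSchedule(c(62, 12000 / 12.5 - 1), 10, "task")
  expect_error(epochTrials(rec, late, c(0, 24)), "trial\\(s\\): 2")
  expect_error(epochTrials(rec, eventSchedule(), c(0, 24)), "empty")
})

test_that("trial averaging equals the direct per-element mean", {
  set.seed(23)
  a <- array(rnorm(20 * 50 * 4), dim = c(20, 50, 4))
  ep <- epochsFromArray(a)
  avg <- averageTrials(ep)
  brute <- matrix(0, 50, 4)
  for (t in 1:50) for (c in 1:4) brute[t, c] <- mean(a[, t, c])
  expect_equal(avg, brute, ignore_attr = TRUE, tolerance = 1e-12)

  # identical epochs average to any one of them; x and -x cancel
  same <- epochsFromArray(array(rep(a[1, , ], each = 5), dim = c(5, 50, 4)))
  expect_equal(averageTrials(same), a[1, , ], ignore_attr = TRUE)
  pmArr <- array(NA_real_, dim = c(2, 50, 4))
  pmArr[1, , ] <- a[1, , ]
  pmArr[2, , ] <- -a[1, , ]
  pm <- epochsFromArray(pmArr)
  expect_lt(max(abs(averageTrials(pm))), 1e-12)

  labeled <- epochsFromArray(a, labels = rep(c("x", "y"), 10))
  expect_equal(averageTrials(labeled, "x"),
               apply(a[seq(1, 19, 2), , ], c(2, 3), mean),
               ignore_attr = TRUE)
  expect_error(averageTrials(labeled, "z"), "label")
})

test_that("epoch-average of a noiseless periodic recording reproduces one period", {
  fsHz <- 12.5
  period <- 20                      # seconds
  onsets <- 60 + period * (0:9)
  t <- (0:(12.5 * 400 - 1)) / fsHz
  x <- sin(2 * pi * t / period)
  rec <- recFromMatrix(matrix(x, ncol = 1), fsHz)
  ep <- epochTrials(rec, eventSchedule(onsets, 10, "task"), c(0, period))
  avg <- averageTrials(ep)
  one <- signalMatrix(rec)[round(onsets[1] * fsHz) + 1:(period * fsHz), 1]
  expect_equal(avg[, 1], one, tolerance = 1e-9)
})
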
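test_that("the paradigm follows the session layout", {
  ev <- makeParadigm(simConfig(seed = 5))
  expect_equal(nTrials(ev), 20L)
  expect_true(all(durations(ev) == 10))
  expect_equal(onsets(ev)[1], 62)            # 60 s lead-in + 2 s cue
  gaps <- diff(onsets(ev))
  expect_true(all(gaps >= 27 & gaps <= 29))  # 2 + 10 + [15, 17]

  # zero jitter collapses to exact arithmetic onsets
  fixed <- makeParadigm(simConfig(restRange = c(15, 15)))
  expect_equal(onsets(fixed), 62 + 27 * (0:19))

  expect_identical(makeParadigm(simConfig(seed = 9)),
                   makeParadigm(simConfig(seed = 9)))
})

test_that("identical configurations give bit-identical sessions", {
  a <- simulateRecording(simConfig(nChannels = 6, nTrials = 4, seed = 13))
  b <- simulateRecording(simConfig(nChannels = 6, nTrials = 4, seed = 13))
  expect_identical(signalMatrix(a$hbo), signalMatrix(b$hbo))
  expect_identical(signalMatrix(a$hbr), signalMatrix(b$hbr))
  expect_identical(a$truth@activeMask, b$truth@activeMask)
  # schedule agrees with the standalone paradigm builder
  expect_identical(onsets(a$truth@events),
                   onsets(makeParadigm(simConfig(nChannels = 6, nTrials = 4,
                                                 seed = 13))))
})

test_that("the noiseless limit is exactly the scaled template, inactive channels zero", {
  cfg <- simConfig(nChannels = 4, nTrials = 3, activeChannels = c(1, 3),
                   activationAmplitude = 1, cardiacAmplitude = 0,
                   respAmplitude = 0, mayerAmplitude = 0, driftSd = 0,
                   whiteSd = 0, seed = 2)
  sim <- simulateRecording(cfg)
  d <- signalMatrix(sim$hbo)
  s <- boxcar(sim$truth@events, cfg$fs, nrow(d))
  want <- desiredHrf(canonicalHrf(cfg$hrf, cfg$fs, 32), s)
  expect_equal(d[, 1], want, tolerance = 1e-12)
  expect_identical(d[, 2], numeric(nrow(d)))
  expect_equal(sim$truth@amplitudes, c(1, 0, 1, 0))
  # HbR is the anti-correlated scaled response
  expect_equal(signalMatrix(sim$hbr)[, 1], -want / 3, tolerance = 1e-12)

  # all amplitudes zero: identically zero channels
  flat <- simulateRecording(simConfig(nChannels = 3, nTrials = 2,
                                      activationAmplitude = 0,
                                      cardiacAmplitude = 0, respAmplitude = 0,
                                      mayerAmplitude = 0, driftSd = 0,
                                      whiteSd = 0, seed = 2))
  expect_true(all(signalMatrix(flat$hbo) == 0))
})

test_that("noise-only channels show spectral peaks at the configured frequencies", {
  cfg <- simConfig(nChannels = 2, nTrials = 10, activationAmplitude = 0,
                   driftSd = 0, whiteSd = 0.01, seed = 17)
  sim <- simulateRecording(cfg)
  v <- signalMatrix(sim$hbo)[, 1]
  sp <- stats::spec.pgram(ts(v, frequency = cfg$fs), plot = FALSE,
                          taper = 0, detrend = TRUE)
  binw <- sp$freq[2] - sp$freq[1]
  for (f0 in c(cfg$cardiacFreq, cfg$respFreq, cfg$mayerFreq)) {
    near <- which(abs(sp$freq - f0) <= binw)
    far <- which(abs(sp$freq - f0) > 5 * binw)
    expect_gt(max(sp$spec[near]), 50 * stats::median(sp$spec[far]))
  }
})

test_that("active-channel z-scores are non-decreasing in activation amplitude", {
  meanActiveZ <- function(amp, seed) {
    cfg <- simConfig(nChannels = 12, nTrials = 8, nActive = 3,
                     activationAmplitude = amp, seed = seed)
    pl <- runSelectionPipeline(cfg)
    zs <- zScoreSelect(pl$avg, pl$template)
    mean(zs@scores[pl$sim$truth@activeMask])
  }
  seeds <- 1:20
  levels <- c(0.01, 0.03, 0.1)
  means <- vapply(levels, function(a)
    mean(vapply(seeds, function(s) meanActiveZ(a, s), numeric(1))),
    numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("selection through the absorbance path matches selection on direct HbO", {
  cfg <- simConfig(nChannels = 10, nTrials = 6, seed = 23)
  sim <- simulateRecording(cfg, absorbance = TRUE)
  direct <- runSelectionPipeline(cfg)
  zDirect <- zScoreSelect(direct$avg, direct$template)

  conv <- mbllConvert(sim$absorbance)
  rec <- savgolSmooth(bandpassFilter(conv$HbO))
  ep <- epochTrials(rec, sim$truth@events, c(0, 24))
  zConv <- zScoreSelect(averageTrials(ep), direct$template)
  expect_identical(isSelected(zConv), isSelected(zDirect))
})

test_that("configuration invariants are enforced", {
  expect_error(simConfig(activeChannels = c(0, 2)), "nChannels")
  expect_error(simConfig(whiteSd = -1), "non-negative")
  expect_error(simConfig(restRange = c(17, 15)), "restRange")
})

test_that("simulator truth serializes to JSON", {
  sim <- simulateRecording(simConfig(nChannels = 4, nTrials = 2, seed = 3))
  path <- file.path(tempdir(), "truth.json")
  writeSimTruth(sim$truth, path)
  doc <- readReport(path)
  expect_equal(doc$active_channels, activeChannels(sim$truth))
  expect_equal(nrow(doc$events), 2L)
})
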
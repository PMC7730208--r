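# Shared fixtures and independent brute-force oracles.

# O(n^2) all-lag cross-correlation: r(tau) = sum_t x[t] * y[t - tau],
# full zero-padded overlap, tau in [-(ny-1), nx-1].
bruteXcorr <- function(x, y) {
  nx <- length(x); ny <- length(y)
  lags <- (1 - ny):(nx - 1)
  r <- vapply(lags, function(tau) {
    s <- 0
    for (j in seq_len(nx)) {
      i <- j - tau
      if (i >= 1 && i <= ny) s <- s + x[j] * y[i]
    }
    s
  }, numeric(1))
  list(lags = lags, r = r)
}

bruteXcorrMax <- function(x, y) {
  b <- bruteXcorr(x, y)
  i <- which(b$r == max(b$r))
  i <- i[order(abs(b$lags[i]), b$lags[i])][1]
  list(r = b$r[i], lag = b$lags[i])
}

# Direct double-loop truncated convolution (0-based index convention):
# out[k] = sum_{n=0..k} hc[n] * s[k - n]
bruteDesiredHrf <- function(hc, s) {
  ns <- length(s)
  out <- numeric(ns)
  for (k in seq_len(ns)) {
    acc <- 0
    for (n in seq_len(k)) {
      if (n <= length(hc)) acc <- acc + hc[n] * s[k - n + 1]
    }
    out[k] <- acc
  }
  out
}

# A recording whose channels are supplied columns
recFromMatrix <- function(m, fsHz = 12.5, chrom = "HbO") {
  NirsRecording(as.matrix(m), fs = fsHz, chromophore = chrom)
}

# Epoch set built directly from a trial x time x channel array
epochsFromArray <- function(a, window = c(0, dim(a)[2] / 12.5), fsHz = 12.5,
                            labels = NULL) {
  if (is.null(labels)) labels <- rep("task", dim(a)[1])
  new("EpochSet", epochs = a, window = window, fs = fsHz,
      trialLabels = labels, channelIds = paste0("ch", seq_len(dim(a)[3])))
}

# Labeled feature matrix from raw values
fmFromValues <- function(v, labels, normalized = FALSE) {
  v <- as.matrix(v)
  if (is.null(colnames(v))) colnames(v) <- paste0("f", seq_len(ncol(v)))
  new("FeatureMatrix", values = v, classLabels = labels,
      normalized = normalized)
}

# Small high-SNR simulated session plus its z-score selection inputs
runSelectionPipeline <- function(cfg) {
  sim <- simulateRecording(cfg)
  rec <- savgolSmooth(bandpassFilter(sim$hbo))
  ep <- epochTrials(rec, sim$truth@events, c(0, 24))
  list(sim = sim, rec = rec, ep = ep, avg = averageTrials(ep),
       template = epochTemplate(fs = cfg$fs))
}
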
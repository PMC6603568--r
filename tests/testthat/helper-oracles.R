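# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: band power by direct periodogram integration,
# correlation/SNR by brute-force definitional sums.

# fraction of total power inside [lo, hi] Hz, rectangular periodogram
bandPowerFraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  nBins <- floor(n / 2)
  f <- (1:nBins) * fs / n
  sel <- f >= lo & f <= hi
  sum(p[1 + which(sel)]) / sum(p[2:(nBins + 1)])
}

# absolute power in a band (unnormalised), for paired comparisons
bandPowerAbs <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  nBins <- floor(n / 2)
  f <- (1:nBins) * fs / n
  sum(p[1 + which(f >= lo & f <= hi)])
}

# brute-force Pearson r straight from the definitional sum
bruteForceR <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sx <- sqrt(sum((x - mx)^2) / (n - 1))
  sy <- sqrt(sum((y - my)^2) / (n - 1))
  acc <- 0
  for (i in seq_len(n)) acc <- acc + (x[i] - mx) / sx * (y[i] - my) / sy
  acc / (n - 1)
}

# brute-force RMS-ratio SNR
bruteForceSnrDb <- function(x, y) {
  num <- sqrt(sum(x^2) / length(x))
  den <- sqrt(sum((x - y)^2) / length(x))
  20 * log10(num / den)
}

# synthetic LCR sweep from known constant parallel-model parameters expressed
# in the meter's series (Re, X) reading
syntheticSweep <- function(reOhm = 1e4, ceF = 1e-6, nPoints = 200,
                           fLo = 20, fHi = 1000, noiseSd = 0,
                           label = "synthetic", location = "frontal",
                           replicate = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- exp(seq(log(fLo), log(fHi), length.out = nPoints))
  re <- rep(reOhm, nPoints)
  x <- -1 / (2 * pi * f * ceF)
  if (noiseSd > 0) {
    re <- re * (1 + stats::rnorm(nPoints, 0, noiseSd))
    x <- x * (1 + stats::rnorm(nPoints, 0, noiseSd))
  }
  impedanceSweep(f, re, x, electrodeLabel = label, location = location,
                 replicateId = replicate)
}

sineEpoch <- function(freq, amp = 1, fs = 250, duration = 30, phase = 0,
                      label = "sine") {
  t <- (0:(round(fs * duration) - 1)) / fs
  EEGEpoch(amp * sin(2 * pi * freq * t + phase), fs = fs, label = label)
}

# small default bench config for tests: fewer epochs than the full bench so
# the suite stays fast, same physics otherwise
testBenchConfig <- function(nEpochs = 3, seed = 11L, ...) {
  benchConfig(
    generator = generatorParams(nEpochs = nEpochs, seed = seed),
    masterSeed = seed, ...
  )
}
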
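# Shared fixtures built in code.

# The worked single-neuron spike train used throughout the binning tests.
workedSpikeTrain <- function() matrix(c(1, 0, 0, 1, 1, 0, 1, 0, 1, 0), ncol = 1)

# A small trained-free 3-layer network and stimulus for structural tests.
tinyNet <- function(model = "alpha", sizes = c(8, 6, 4), seed = 7) {
  spikeNetwork(sizes, model = model, inputTuning = "quadrant_2d", seed = seed)
}

tinyStim <- function(duration = 250, seed = 3) {
  sumOfSines(4, 20, duration = duration, seed = seed)
}

# Correlated bivariate Gaussian sample with known mutual information
# -0.5 * log2(1 - rho^2).
gaussPair <- function(n, rho, seed) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  list(x = x, y = y, mi = -0.5 * log2(1 - rho^2))
}

# Raster whose spike count per window deterministically encodes a
# discretized stimulus while spike placement within the window is random:
# a pure count code.
countCodeRaster <- function(nWindows = 400, T = 50, levels = 4, seed = 1) {
  set.seed(seed)
  sWin <- sample(seq_len(levels), nWindows, replace = TRUE)
  spikes <- numeric(nWindows * T)
  for (w in seq_len(nWindows)) {
    pos <- sample(T, sWin[w])
    spikes[(w - 1) * T + pos] <- 1
  }
  stim <- matrix(rep(sWin + rnorm(nWindows, 0, 0.01), each = T), ncol = 1)
  list(spikes = spikes, stimulus = stim)
}

# Raster with exactly one spike per window whose latency encodes the
# stimulus: a pure timing (latency) code.
latencyCodeRaster <- function(nWindows = 400, T = 50, seed = 2) {
  set.seed(seed)
  sWin <- runif(nWindows)
  lat <- pmin(T - 1, pmax(0, round(sWin * (T - 1))))
  spikes <- numeric(nWindows * T)
  spikes[(seq_len(nWindows) - 1) * T + lat + 1] <- 1
  stim <- matrix(rep(sWin, each = T), ncol = 1)
  list(spikes = spikes, stimulus = stim)
}
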
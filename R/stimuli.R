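#' Synthetic time-dependent stimuli
#'
#' Generators for every stimulus class used in the network experiments:
#' sums of two sines, single sines, Gaussian white noise, binary telegraph
#' signals, and noise-corrupted versions of any of these. All stimuli are
#' sampled on a regular 1 ms (by default) grid and are deterministic under a
#' fixed seed. By default the compound waveform is normalized to
#' max |value| = 1 so firing regimes are comparable across stimulus types.
#'
#' @name stimuli
NULL

newStimulus <- function(values, dt, components = list(), clean = NULL,
                        seed = NA_integer_) {
  new("Stimulus", values = values, dt = dt, components = components,
      clean = clean, seed = as.integer(seed))
}

checkDuration <- function(duration, dt) {
  stopIfNot(duration > 0 && dt > 0, "duration and dt must be positive")
  nt <- duration / dt
  stopIfNot(abs(nt - round(nt)) < 1e-9, "duration must be an integer multiple of dt")
  as.integer(round(nt))
}

#' Sum-of-sines stimulus
#'
#' Two-term sinusoidal stimulus with a slow component at `fLow` and a fast
#' component at `fHigh` in every channel. Each additive term is retained as a
#' named component ("low", "high") so the two frequency bands can be decoded
#' separately. With `ds = 2` the channels share frequencies but get
#' independent random phases (drawn from the seed) unless phases are given.
#'
#' @param fLow,fHigh component frequencies in Hz, `fLow < fHigh`.
#' @param duration duration in ms.
#' @param dt time step in ms (default 1).
#' @param amplitudes length-2 amplitudes of the (low, high) terms.
#' @param phases optional length-2 phase offsets (radians) shared by all
#'   channels; if `NULL`, phases are drawn uniformly per channel and term.
#' @param ds number of channels (1 or 2).
#' @param normalize logical; scale the compound waveform (and its components
#'   by the same factor) to max |value| = 1.
#' @param seed integer seed for random phases.
#' @return a [Stimulus-class] object.
#' @export
#' @examples
#' s <- sumOfSines(4, 20, duration = 1000, seed = 1)
#' dim(stimValues(s))
sumOfSines <- function(fLow, fHigh, duration, dt = 1,
                       amplitudes = c(1, 1), phases = NULL, ds = 2,
                       normalize = TRUE, seed = NA_integer_) {
  stopIfNot(fLow > 0 && fHigh > 0, "frequencies must be positive")
  stopIfNot(fLow < fHigh, "fLow must be less than fHigh")
  stopIfNot(duration >= 1000 / fLow, "duration must cover one period of fLow")
  stopIfNot(ds %in% c(1, 2), "ds must be 1 or 2")
  nt <- checkDuration(duration, dt)
  tms <- (seq_len(nt) - 1L) * dt
  ph <- withSeed(seed, {
    if (is.null(phases)) matrix(stats::runif(2 * ds, 0, 2 * pi), 2, ds)
    else matrix(rep(phases, ds), 2, ds)
  })
  low <- sapply(seq_len(ds), function(ch)
    amplitudes[1] * sin(2 * pi * fLow * tms / 1000 + ph[1, ch]))
  high <- sapply(seq_len(ds), function(ch)
    amplitudes[2] * sin(2 * pi * fHigh * tms / 1000 + ph[2, ch]))
  low <- matrix(low, nt, ds); high <- matrix(high, nt, ds)
  v <- low + high
  if (normalize) {
    m <- max(abs(v))
    if (m > 0) { v <- v / m; low <- low / m; high <- high / m }
  }
  newStimulus(v, dt, components = list(low = low, high = high), seed = seed)
}

#' Single-sine stimulus
#'
#' One sinusoid of frequency `f` Hz in every channel (amplitude 1, phase 0
#' by default), e.g. the 1 Hz flower-tracking stimulus used to probe the
#' five-layer moth pathway model.
#'
#' @param f frequency in Hz.
#' @param duration duration in ms.
#' @param dt time step in ms.
#' @param amplitude amplitude.
#' @param phase phase offset (radians).
#' @param ds channel count (1 or 2).
#' @return a [Stimulus-class] object.
#' @export
singleSine <- function(f, duration, dt = 1, amplitude = 1, phase = 0, ds = 1) {
  stopIfNot(f > 0, "frequency must be positive")
  stopIfNot(ds %in% c(1, 2), "ds must be 1 or 2")
  nt <- checkDuration(duration, dt)
  tms <- (seq_len(nt) - 1L) * dt
  col <- amplitude * sin(2 * pi * f * tms / 1000 + phase)
  v <- matrix(rep(col, ds), nt, ds)
  newStimulus(v, dt, components = list(sine = v))
}

#' Gaussian white-noise stimulus
#'
#' Independent N(0, sigma^2) draws per time step and channel.
#'
#' @param duration duration in ms.
#' @param dt time step in ms.
#' @param sigma noise SD (> 0).
#' @param ds channel count.
#' @param seed integer seed.
#' @return a [Stimulus-class] object.
#' @export
whiteNoise <- function(duration, dt = 1, sigma = 0.5, ds = 1, seed = NA_integer_) {
  stopIfNot(sigma > 0, "sigma must be positive")
  stopIfNot(ds %in% c(1, 2), "ds must be 1 or 2")
  nt <- checkDuration(duration, dt)
  v <- withSeed(seed, matrix(stats::rnorm(nt * ds, 0, sigma), nt, ds))
  newStimulus(v, dt, seed = seed)
}

#' Binary telegraph stimulus
#'
#' Piecewise-constant two-level signal that switches between `levels` at
#' exponentially distributed dwell times with mean `1/switchRate`.
#'
#' @param duration duration in ms.
#' @param dt time step in ms.
#' @param switchRate expected switches per ms (mean dwell = 1/switchRate ms).
#' @param levels the two signal levels (must differ).
#' @param ds channel count.
#' @param seed integer seed.
#' @return a [Stimulus-class] object.
#' @export
binaryTelegraph <- function(duration, dt = 1, switchRate = 0.01,
                            levels = c(-1, 1), ds = 1, seed = NA_integer_) {
  stopIfNot(switchRate > 0, "switchRate must be positive")
  stopIfNot(levels[1] != levels[2], "the two levels must differ")
  stopIfNot(ds %in% c(1, 2), "ds must be 1 or 2")
  nt <- checkDuration(duration, dt)
  v <- withSeed(seed, {
    out <- matrix(0, nt, ds)
    for (ch in seq_len(ds)) {
      state <- sample(c(1L, 2L), 1L)
      t <- 0
      col <- numeric(nt)
      while (t < nt) {
        dwell <- max(1L, ceiling(stats::rexp(1, rate = switchRate) / dt))
        idx <- seq.int(t + 1L, min(nt, t + dwell))
        col[idx] <- levels[state]
        state <- 3L - state
        t <- t + dwell
      }
      out[, ch] <- col
    }
    out
  })
  newStimulus(v, dt, seed = seed)
}

#' Add white noise to a stimulus
#'
#' Returns `s + N(0, sigma^2)` noise, retaining the original waveform as the
#' noiseless target (`cleanTarget`), so networks can be driven by the noisy
#' version while being trained and decoded against the clean one.
#'
#' @param s a [Stimulus-class].
#' @param sigma noise SD (>= 0); 0 returns an identical stimulus.
#' @param seed integer seed.
#' @return a [Stimulus-class] with the clean target retained.
#' @export
addNoise <- function(s, sigma, seed = NA_integer_) {
  stopIfNot(is(s, "Stimulus"), "s must be a Stimulus")
  stopIfNot(sigma >= 0, "sigma must be non-negative")
  v <- stimValues(s)
  if (sigma == 0) {
    return(newStimulus(v, timeStep(s), components = stimComponents(s),
                       clean = v, seed = seed))
  }
  noisy <- v + withSeed(seed, matrix(stats::rnorm(length(v), 0, sigma),
                                     nrow(v), ncol(v)))
  newStimulus(noisy, timeStep(s), components = stimComponents(s),
              clean = v, seed = seed)
}

#' Write a stimulus as a columnar text table
#'
#' @param s a [Stimulus-class].
#' @param path output file path (TSV with columns time_ms, ch1[, ch2]).
#' @return the path, invisibly.
#' @export
writeStimulus <- function(s, path) {
  v <- stimValues(s)
  df <- data.frame(time_ms = (seq_len(nrow(v)) - 1L) * timeStep(s))
  for (ch in seq_len(ncol(v))) df[[paste0("ch", ch)]] <- v[, ch]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
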
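#' Sliding-window spike binning
#'
#' Converts a spike raster into a decoder-ready tensor. A rectangular window
#' of width `T` ms slides along the raster in steps of `stride`; the spikes
#' inside each window are sub-divided into bins of width `deltaT` ms and
#' counted. With `deltaT = 1` the windows are the raw binary spike trains;
#' with `deltaT = T` each window collapses to a single spike count per
#' neuron. The stimulus value at the start of each window is stored as the
#' decoding target for that window.
#'
#' @param raster a [SpikeRaster-class] (or plain binary matrix, Nt x Nnrn).
#' @param stimulus a [Stimulus-class] or numeric matrix aligned with the
#'   raster rows; the noiseless target is used when one is retained.
#' @param T window width in ms.
#' @param deltaT bin width in ms; must divide `T`.
#' @param stride window stride in steps (default 1).
#' @return a [BinnedResponse-class].
#' @export
#' @examples
#' rho <- matrix(c(1, 0, 0, 1, 1, 0, 1, 0, 1, 0), ncol = 1)
#' br <- binSpikes(rho, matrix(0, 10, 1), T = 8, deltaT = 4)
#' binTensor(br)[, 1, ]
binSpikes <- function(raster, stimulus, T, deltaT, stride = 1L) {
  sp <- if (is(raster, "SpikeRaster")) spikeMatrix(raster) else as.matrix(raster)
  sv <- if (is(stimulus, "Stimulus")) cleanTarget(stimulus) else as.matrix(stimulus)
  nt <- nrow(sp)
  stopIfNot(T <= nt, "window T exceeds raster length")
  stopIfNot(T %% deltaT == 0, "T must be divisible by deltaT")
  stopIfNot(nrow(sv) >= nt - 0L, "stimulus must cover the raster")
  stride <- as.integer(stride)
  stopIfNot(stride >= 1L, "stride must be >= 1")
  nbins <- as.integer(T / deltaT)
  nnrn <- ncol(sp)
  starts <- seq.int(1L, nt - T + 1L, by = stride)
  ns <- length(starts)
  # counts in bin b of window w = difference of cumulative sums at the
  # bin edges; vectorized over windows and neurons
  cs <- rbind(0, apply(sp, 2L, cumsum))          # (nt + 1) x nnrn
  tens <- array(0, dim = c(ns, nnrn, nbins))
  for (b in seq_len(nbins)) {
    lo <- starts + (b - 1L) * deltaT             # bin start (1-based row)
    hi <- starts + b * deltaT                    # one past bin end
    tens[, , b] <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  }
  new("BinnedResponse", tensor = tens, windowMs = T, deltaT = deltaT,
      stride = stride,
      alignedStimulus = sv[starts, , drop = FALSE])
}

#' Non-overlapping response windows for single-neuron analysis
#'
#' Chops a single neuron's spike train into consecutive non-overlapping
#' windows of width `T` ms (mirroring wingstrokes) and returns per-window
#' spike counts together with the within-window spike times. Windows beyond
#' the last complete one are truncated (with a message).
#'
#' @param spikes binary vector (one neuron's spike train at 1 ms steps) or a
#'   single-column [SpikeRaster-class].
#' @param T window width in ms.
#' @param pad sentinel used to pad timing rows with fewer spikes than the
#'   maximum count; lies outside [0, T) so it can never be mistaken for a
#'   spike time, and the decomposition conditions on exact counts so padding
#'   never enters an estimate.
#' @return list with `counts` (integer vector, length Nt %/% T) and `times`
#'   (matrix NT x max count, within-window spike times in ms, padded).
#' @export
nonoverlappingWindows <- function(spikes, T, pad = -1) {
  v <- if (is(spikes, "SpikeRaster")) spikeMatrix(spikes) else spikes
  v <- as.numeric(as.matrix(v))
  nT <- length(v) %/% T
  stopIfNot(nT >= 1, "raster shorter than one window")
  if (length(v) %% T != 0) {
    message(sprintf("truncating %d trailing steps (< one window)", length(v) %% T))
  }
  v <- v[seq_len(nT * T)]
  counts <- as.integer(colSums(matrix(v, nrow = T)))
  cmax <- max(counts)
  times <- matrix(pad, nT, max(cmax, 1L))
  if (cmax > 0L) {
    for (w in which(counts > 0L)) {
      idx <- which(v[((w - 1L) * T + 1L):(w * T)] == 1) - 1L  # time within window
      times[w, seq_along(idx)] <- idx
    }
  }
  list(counts = counts, times = times)
}
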
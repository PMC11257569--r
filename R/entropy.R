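#' Maximum-entropy bounds for spike count and spike timing codes
#'
#' With a response window of `T` ms and an absolute refractory period of
#' `tauRef` ms, a neuron can place spikes into `nbins = T / tauRef` slots.
#' A count code distinguishes only the number of spikes (nbins + 1 outcomes)
#' while a timing code distinguishes every binary occupancy pattern
#' (2^nbins outcomes). Assuming all outcomes equiprobable gives closed-form
#' entropy upper bounds: `log2(nbins + 1)` bits for the count code and
#' `nbins` bits for the timing code, each scaling linearly in population
#' size. The timing bound dominates the count bound for every nbins >= 1,
#' with equality only at nbins = 1.
#'
#' @param T response-window duration in ms.
#' @param tauRef refractory period in ms; must divide `T` exactly.
#' @param nNeurons population size.
#' @return entropy bound in bits per window.
#' @name entropyBounds
NULL

entropyParams <- function(T, tauRef, nNeurons) {
  stopIfNot(T > 0 && tauRef > 0 && nNeurons >= 1, "all parameters must be positive")
  nb <- T / tauRef
  stopIfNot(abs(nb - round(nb)) < 1e-9, "T must be an integer multiple of tauRef")
  list(nbins = as.integer(round(nb)), nNeurons = as.integer(nNeurons))
}

#' @rdname entropyBounds
#' @export
countEntropyBound <- function(T, tauRef, nNeurons = 1) {
  p <- entropyParams(T, tauRef, nNeurons)
  p$nNeurons * log2(p$nbins + 1)
}

#' @rdname entropyBounds
#' @export
timingEntropyBound <- function(T, tauRef, nNeurons = 1) {
  p <- entropyParams(T, tauRef, nNeurons)
  as.numeric(p$nNeurons) * p$nbins
}

#' Enumerate spike-code outcomes explicitly
#'
#' Brute-force enumeration of all population count-code outcomes
#' ((nbins + 1)^Nnrn count vectors) and timing-code outcomes
#' (2^(nbins * Nnrn) binary words), as an independent check of the
#' closed-form bounds: log2 of each outcome count equals the respective
#' bound exactly.
#'
#' @inheritParams entropyBounds
#' @return list with `countOutcomes` and `timingOutcomes` (integer counts).
#' @export
enumerateOutcomes <- function(T, tauRef, nNeurons = 1) {
  p <- entropyParams(T, tauRef, nNeurons)
  stopIfNot(p$nbins * p$nNeurons <= 20, "enumeration too large (nbins * Nnrn > 20)")
  # count code: per-neuron counts 0..nbins, enumerated as tuples
  countGrid <- do.call(expand.grid, rep(list(0:p$nbins), p$nNeurons))
  # timing code: every binary occupancy pattern across all neuron-bins
  nSlots <- p$nbins * p$nNeurons
  timingGrid <- do.call(expand.grid, rep(list(0:1), nSlots))
  list(countOutcomes = nrow(unique(countGrid)),
       timingOutcomes = nrow(unique(timingGrid)))
}

#' Tabulate entropy bounds over population size
#'
#' Columnar report of count and timing entropy bounds (per window and per
#' ms) as a function of population size for fixed window and refractory
#' parameters.
#'
#' @inheritParams entropyBounds
#' @param nNeuronsGrid vector of population sizes.
#' @return data.frame with columns nNeurons, countBits, timingBits,
#'   countRate, timingRate (bits/ms).
#' @export
entropyBoundTable <- function(T, tauRef, nNeuronsGrid = 1:20) {
  rows <- lapply(nNeuronsGrid, function(n) {
    cb <- countEntropyBound(T, tauRef, n)
    tb <- timingEntropyBound(T, tauRef, n)
    data.frame(nNeurons = n, countBits = cb, timingBits = tb,
               countRate = cb / T, timingRate = tb / T)
  })
  do.call(rbind, rows)
}
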
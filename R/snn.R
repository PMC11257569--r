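#' Quadrant-tuned 2-D input encoding
#'
#' Maps a two-channel stimulus (sx, sy) — the position of a moving object in
#' the visual scene — onto input currents for `nIn` motion-sensitive
#' neurons, split into four equal subpopulations tuned to the four quadrants
#' of the plane. Neuron i of quadrant q receives current sqrt(sx^2 + sy^2)
#' at time t iff the offset-shifted point (sx - o_{q,i}, sy - o_{q,i}) lies
#' strictly inside quadrant q, and 0 otherwise. Points on a quadrant
#' boundary (either shifted coordinate exactly 0) drive no one. The random
#' per-neuron offsets o ~ N(0, 0.1) smooth the hand-off between
#' subpopulations.
#'
#' @param s a [Stimulus-class] with 2 channels, or an Nt x 2 matrix.
#' @param nIn number of input neurons, divisible by 4.
#' @param offsets optional numeric vector of length `nIn` of tuning offsets;
#'   if `NULL`, drawn as N(0, `offsetVar`) under `seed`.
#' @param offsetVar variance (or SD, per `convention`) of the offset
#'   distribution.
#' @param convention how the second parameter of the normal is read
#'   ("variance" or "sd").
#' @param seed integer seed for the offsets.
#' @return list with `current` (Nt x nIn matrix) and `offsets`.
#' @export
encodeInput2d <- function(s, nIn, offsets = NULL, offsetVar = 0.1,
                          convention = "variance", seed = NA_integer_) {
  v <- if (is(s, "Stimulus")) stimValues(s) else as.matrix(s)
  stopIfNot(ncol(v) == 2L, "2-D encoding requires a 2-channel stimulus")
  stopIfNot(nIn %% 4L == 0L, "nIn must be divisible by 4")
  if (is.null(offsets)) {
    offsets <- withSeed(seed, rnormConv(nIn, 0, offsetVar, convention))
  }
  stopIfNot(length(offsets) == nIn, "need one offset per input neuron")
  nt <- nrow(v)
  perQ <- nIn %/% 4L
  mag <- sqrt(v[, 1]^2 + v[, 2]^2)
  cur <- matrix(0, nt, nIn)
  # quadrant membership of the shifted point, per neuron (offset applied to
  # both coordinates); strict inequalities leave boundary points silent
  for (i in seq_len(nIn)) {
    q <- (i - 1L) %/% perQ + 1L
    x <- v[, 1] - offsets[i]
    y <- v[, 2] - offsets[i]
    inQ <- switch(q,
      x > 0 & y > 0,
      x < 0 & y > 0,
      x < 0 & y < 0,
      x > 0 & y < 0)
    cur[inQ, i] <- mag[inQ]
  }
  list(current = cur, offsets = offsets)
}

#' Direction-tuned 1-D input encoding
#'
#' One-dimensional analogue of [encodeInput2d()] for a single-channel
#' stimulus: the input population splits into two equal subpopulations tuned
#' to the two motion directions along a line. A neuron of the positive
#' subpopulation receives current |s| when its offset-shifted stimulus is
#' > 0; the negative subpopulation responds when it is < 0; s exactly at the
#' offset drives no one.
#'
#' @param s a [Stimulus-class] with 1 channel, or an Nt x 1 matrix.
#' @param nIn number of input neurons, divisible by 2.
#' @inheritParams encodeInput2d
#' @return list with `current` (Nt x nIn matrix) and `offsets`.
#' @export
encodeInput1d <- function(s, nIn, offsets = NULL, offsetVar = 0.1,
                          convention = "variance", seed = NA_integer_) {
  v <- if (is(s, "Stimulus")) stimValues(s) else as.matrix(s)
  stopIfNot(ncol(v) == 1L, "1-D encoding requires a 1-channel stimulus")
  stopIfNot(nIn %% 2L == 0L, "nIn must be divisible by 2")
  if (is.null(offsets)) {
    offsets <- withSeed(seed, rnormConv(nIn, 0, offsetVar, convention))
  }
  stopIfNot(length(offsets) == nIn, "need one offset per input neuron")
  nt <- nrow(v)
  half <- nIn %/% 2L
  mag <- abs(v[, 1])
  cur <- matrix(0, nt, nIn)
  for (i in seq_len(nIn)) {
    x <- v[, 1] - offsets[i]
    sel <- if (i <= half) x > 0 else x < 0
    cur[sel, i] <- mag[sel]
  }
  list(current = cur, offsets = offsets)
}

#' Sparse signed synaptic weight matrix
#'
#' Each entry is non-zero with probability `p`; non-zero entries are drawn
#' from N(0, 1/(p * Npre)) (variance convention by default). Excitatory and
#' inhibitory connections are equally probable and may coexist for the same
#' presynaptic neuron (Dale's law deliberately not enforced).
#'
#' @param nPre,nPost pre- and post-synaptic layer sizes.
#' @param p connection probability in (0, 1].
#' @param convention "variance" or "sd" reading of the N(0, 1/(p Npre))
#'   parameter.
#' @param seed integer seed.
#' @return nPre x nPost numeric matrix.
#' @export
makeWeights <- function(nPre, nPost, p = 0.7, convention = "variance",
                        seed = NA_integer_) {
  stopIfNot(p > 0 && p <= 1, "p must be in (0, 1]")
  withSeed(seed, {
    mask <- matrix(stats::runif(nPre * nPost) < p, nPre, nPost)
    w <- matrix(rnormConv(nPre * nPost, 0, 1 / (p * nPre), convention),
                nPre, nPost)
    w * mask
  })
}

# Per-layer neuron parameter draws. Alpha model: alpha ~ U(0.7, 0.9),
# beta = alpha - 0.1, Uthr ~ U(0, 0.5). LIF: beta ~ U(0.7, 0.9),
# Uthr ~ U(0, 1.1). Ureset = 0 for both.
drawNeuronParams <- function(n, model) {
  if (model == "alpha") {
    a <- stats::runif(n, 0.7, 0.9)
    list(alpha = a, beta = a - 0.1, uThr = stats::runif(n, 0, 0.5))
  } else {
    list(alpha = rep(NA_real_, n), beta = stats::runif(n, 0.7, 0.9),
         uThr = stats::runif(n, 0, 1.1))
  }
}

#' Build a feedforward spiking network
#'
#' Draws per-neuron dynamical parameters, sparse signed weights and input
#' tuning offsets for a feedforward network of alpha (spike-response) or
#' leaky integrate-and-fire neurons, plus the dual count/timing readout used
#' during training.
#'
#' @param layerSizes integer vector of layer sizes (input first).
#' @param model "alpha" (default) or "lif".
#' @param p connection probability (default 0.7).
#' @param inputTuning "quadrant_2d" (2-channel stimuli) or "direction_1d".
#' @param ds stimulus channel count the readout maps to (1 or 2).
#' @param gamma readout mixing weight between timing and count readouts.
#' @param convention "variance" or "sd" reading of N(0, v) parameters.
#' @param seed integer seed; the network is reproducible from it.
#' @return a [SpikeNetwork-class].
#' @export
spikeNetwork <- function(layerSizes, model = c("alpha", "lif"), p = 0.7,
                         inputTuning = c("quadrant_2d", "direction_1d"),
                         ds = if (match.arg(inputTuning) == "quadrant_2d") 2L else 1L,
                         gamma = 0.5, convention = "variance",
                         seed = NA_integer_) {
  model <- match.arg(model)
  inputTuning <- match.arg(inputTuning)
  layerSizes <- as.integer(layerSizes)
  nL <- length(layerSizes)
  built <- withSeed(seed, {
    neurons <- lapply(layerSizes, drawNeuronParams, model = model)
    weights <- lapply(seq_len(nL - 1L), function(k) {
      makeWeights(layerSizes[k], layerSizes[k + 1L], p, convention)
    })
    offsets <- rnormConv(layerSizes[1L], 0, 0.1, convention)
    nOut <- layerSizes[nL]
    readout <- list(
      Wtime = matrix(rnormConv(nOut * ds, 0, 0.1, convention), nOut, ds),
      Wcount = matrix(rnormConv(nOut * ds, 0, 0.1, convention), nOut, ds),
      gamma = gamma,
      Ktime = readoutKernel(10, 0.1),
      Kcount = readoutKernel(70, 0.1))
    list(neurons = neurons, weights = weights, offsets = offsets,
         readout = readout)
  })
  new("SpikeNetwork", layerSizes = layerSizes, model = model, p = p,
      inputTuning = inputTuning, neurons = built$neurons,
      weights = built$weights, offsets = built$offsets,
      readout = built$readout, normConvention = convention,
      seed = as.integer(seed))
}

# tau_alpha = ln(alpha) / (ln(beta) - ln(alpha)) + 1, the membrane time
# constant of the alpha (spike-response) neuron.
tauAlpha <- function(alpha, beta) log(alpha) / (log(beta) - log(alpha)) + 1

#' One simulation step of a layer of alpha neurons
#'
#' Updates the excitatory and inhibitory current traces and the membrane
#' potential, emits spikes where U > Uthr (strict), and resets membrane and
#' both current traces of the spiking neurons.
#'
#' @param state list with numeric vectors `iExc`, `iInh`, `u` (or `NULL` for
#'   a zero initial state).
#' @param iIn input-current vector.
#' @param params list with per-neuron `alpha`, `beta`, `uThr`.
#' @return list with updated `state` and binary `spikes` vector.
#' @export
stepAlpha <- function(state, iIn, params) {
  n <- length(iIn)
  if (is.null(state)) state <- list(iExc = numeric(n), iInh = numeric(n),
                                    u = numeric(n))
  stopIfNot(all(is.finite(c(state$iExc, state$iInh, iIn))), "non-finite state")
  iExc <- params$alpha * state$iExc + iIn
  iInh <- params$beta * state$iInh - iIn
  u <- tauAlpha(params$alpha, params$beta) * (iExc + iInh)
  spk <- as.numeric(u > params$uThr)
  keep <- 1 - spk
  list(state = list(iExc = iExc * keep, iInh = iInh * keep, u = u * keep),
       spikes = spk)
}

#' One simulation step of a layer of LIF neurons
#'
#' Membrane update U[t+1] = beta U[t] + Iin[t+1], spike where U > Uthr
#' (strict), reset to 0 on spike.
#'
#' @inheritParams stepAlpha
#' @return list with updated `state` and binary `spikes` vector.
#' @export
stepLif <- function(state, iIn, params) {
  n <- length(iIn)
  if (is.null(state)) state <- list(u = numeric(n))
  stopIfNot(all(is.finite(c(state$u, iIn))), "non-finite state")
  u <- params$beta * state$u + iIn
  spk <- as.numeric(u > params$uThr)
  list(state = list(u = u * (1 - spk)), spikes = spk)
}

# Simulate one layer over all time steps given its input current matrix.
# Returns the binary raster (Nt x n). The time recursion runs in compiled
# code; stepAlpha/stepLif are the single-step reference implementations.
runLayer <- function(current, params, model) {
  stopIfNot(all(is.finite(current)), "non-finite input current")
  if (model == "alpha") {
    .layerForwardAlphaCpp(current, params$alpha, params$beta, params$uThr,
                          25, TRUE)$S
  } else {
    .layerForwardLifCpp(current, params$beta, params$uThr, 25, TRUE)$S
  }
}

#' Simulate a feedforward spiking network
#'
#' Encodes the stimulus into input currents, runs the input layer, then
#' propagates spikes forward: layer k+1 at step t receives the weighted
#' spikes of layer k at step t. Returns one [SpikeRaster-class] per layer
#' (input included).
#'
#' @param net a [SpikeNetwork-class].
#' @param s a [Stimulus-class] whose channel count matches the input tuning.
#' @return named list of [SpikeRaster-class] objects.
#' @export
simulateNetwork <- function(net, s) {
  enc <- if (net@inputTuning == "quadrant_2d") {
    encodeInput2d(s, net@layerSizes[1L], offsets = net@offsets)
  } else {
    encodeInput1d(s, net@layerSizes[1L], offsets = net@offsets)
  }
  nL <- length(net@layerSizes)
  rasters <- vector("list", nL)
  cur <- enc$current
  for (k in seq_len(nL)) {
    rasters[[k]] <- runLayer(cur, net@neurons[[k]], net@model)
    if (k < nL) cur <- rasters[[k]] %*% net@weights[[k]]
  }
  labels <- layerLabels(nL)
  out <- lapply(seq_len(nL), function(k) {
    new("SpikeRaster", spikes = rasters[[k]], dt = timeStep(s),
        label = labels[k])
  })
  names(out) <- labels
  out
}

# Conventional layer labels: input / hidden-i / output for 3 layers,
# input / E1 / B / E2 / output for 5 (expand-bottleneck-expand-converge).
layerLabels <- function(nL) {
  if (nL == 3L) c("input", "hidden", "output")
  else if (nL == 5L) c("input", "E1", "B", "E2", "output")
  else c("input", paste0("hidden", seq_len(nL - 2L)), "output")
}

#' Write rasters as an event-list text table
#'
#' @param rasters list of [SpikeRaster-class] as returned by
#'   [simulateNetwork()].
#' @param path output TSV path with columns layer, neuron, time_ms.
#' @return the path, invisibly.
#' @export
writeEventList <- function(rasters, path) {
  rows <- lapply(rasters, function(r) {
    sp <- spikeMatrix(r)
    idx <- which(sp == 1, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(layer = layerLabel(r), neuron = idx[, 2],
               time_ms = (idx[, 1] - 1) * r@dt)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(layer = character(), neuron = integer(),
                                    time_ms = numeric())
  utils::write.table(df[order(df$layer, df$time_ms, df$neuron), ], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
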
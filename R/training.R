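#' Readout convolution kernel
#'
#' Truncated Gaussian-shaped kernel K(t) = exp[-(t - deltaT/2)^2 * sigma]
#' on the open support 0 < t < deltaT and 0 outside, peaking at t =
#' deltaT/2. `sigma` multiplies the squared deviation exactly as written
#' (an inverse-width in 1/ms^2); see the methods vignette for the
#' convention. The default supports are 10 ms (timing readout, typically
#' 1-3 spikes) and 70 ms (count readout, several spikes).
#'
#' @param deltaT kernel support in ms.
#' @param sigma inverse-width multiplier of the squared deviation (> 0).
#' @param dt sampling step in ms.
#' @return numeric vector of length deltaT/dt, sampled at t = dt, 2 dt, ...
#' @export
#' @examples
#' readoutKernel(10, 0.1)[5]  # peak, exp(0) = 1
readoutKernel <- function(deltaT, sigma = 0.1, dt = 1) {
  stopIfNot(sigma > 0, "sigma must be positive")
  tgrid <- seq(dt, deltaT, by = dt)
  k <- exp(-(tgrid - deltaT / 2)^2 * sigma)
  k[tgrid <= 0 | tgrid >= deltaT] <- 0
  k
}

# Causal convolution of a (Nt x n) matrix with a kernel vector:
# out[t, ] = sum_u K[u] * x[t - u + 1, ].
convCausal <- function(x, k) {
  nt <- nrow(x)
  out <- matrix(0, nt, ncol(x))
  for (u in seq_along(k)) {
    if (k[u] == 0) next
    out[u:nt, ] <- out[u:nt, ] + k[u] * x[seq_len(nt - u + 1L), , drop = FALSE]
  }
  out
}

# Adjoint of convCausal: gx[tau, ] = sum_u K[u] * gout[tau + u - 1, ].
convCausalAdj <- function(gout, k) {
  nt <- nrow(gout)
  gx <- matrix(0, nt, ncol(gout))
  for (u in seq_along(k)) {
    if (k[u] == 0) next
    gx[seq_len(nt - u + 1L), ] <- gx[seq_len(nt - u + 1L), ] +
      k[u] * gout[u:nt, , drop = FALSE]
  }
  gx
}

#' Dual count/timing readout of the output layer
#'
#' z = gamma * (Ktime * P) Wtime + (1 - gamma) * (Kcount * P) Wcount, where
#' `*` is causal convolution of the binary output spikes with the timing
#' (10 ms) and count (70 ms) kernels. With gamma = 0.5 (the default built
#' into [spikeNetwork()]) count- and timing-based readouts are weighed
#' equally, so training does not bias the network toward either coding
#' strategy.
#'
#' @param raster output-layer [SpikeRaster-class] or binary matrix.
#' @param readout list with `Wtime`, `Wcount`, `gamma`, `Ktime`, `Kcount`
#'   (as stored in a [SpikeNetwork-class]).
#' @return numeric matrix (Nt x ds).
#' @export
readoutSignal <- function(raster, readout) {
  p <- if (is(raster, "SpikeRaster")) spikeMatrix(raster) else as.matrix(raster)
  stopIfNot(nrow(readout$Wtime) == ncol(p), "readout weights do not match layer size")
  rt <- convCausal(p, readout$Ktime)
  rc <- convCausal(p, readout$Kcount)
  readout$gamma * (rt %*% readout$Wtime) +
    (1 - readout$gamma) * (rc %*% readout$Wcount)
}

#' Mean-squared-error training loss
#'
#' Mean over time steps and channels of (z - s)^2.
#'
#' @param z readout matrix (Nt x ds).
#' @param s target [Stimulus-class] or matrix of the same shape.
#' @return non-negative scalar.
#' @export
lossMse <- function(z, s) {
  sv <- if (is(s, "Stimulus")) cleanTarget(s) else as.matrix(s)
  stopIfNot(all(dim(z) == dim(sv)), "readout and target shapes differ")
  mean((z - sv)^2)
}

# Fast-sigmoid surrogate derivative d spike / d (U - Uthr).
surrGrad <- function(x, slope) 1 / (1 + slope * abs(x))^2

# Soft spike used only by the relaxed (fully differentiable) mode:
# 0.5 * (1 + x / (1 + slope |x|)), whose derivative is surrGrad / 2... no:
# d/dx [x / (1 + k|x|)] = 1 / (1 + k|x|)^2, so softSpike' = 0.5 * surrGrad.
softSpike <- function(x, slope) 0.5 * (1 + x / (1 + slope * abs(x)))

# Forward simulation with full caches. hard = TRUE: binary spikes, state
# reset on spike (reset detached in backward). hard = FALSE: relaxed mode
# with soft spikes and no reset, smooth end to end (used to validate the
# adjoint code against finite differences). The per-step recursions run in
# compiled code; layer-to-layer propagation (matmuls) stays in R/BLAS.
snnForward <- function(net, current, slope = 25, hard = TRUE) {
  nL <- length(net@layerSizes)
  caches <- vector("list", nL)
  cur <- current
  for (k in seq_len(nL)) {
    np <- net@neurons[[k]]
    if (net@model == "alpha") {
      caches[[k]] <- .layerForwardAlphaCpp(cur, np$alpha, np$beta, np$uThr,
                                           slope, hard)
    } else {
      caches[[k]] <- .layerForwardLifCpp(cur, np$beta, np$uThr, slope, hard)
    }
    if (k < nL) cur <- caches[[k]]$S %*% net@weights[[k]]
  }
  caches
}

# Backward sweep of one layer: given dL/dS (Nt x n), return dL/dIin,
# dL/dalpha, dL/dbeta. Resets are treated as constants (detached).
layerBackward <- function(net, k, cache, gS, slope, hard = TRUE) {
  np <- net@neurons[[k]]
  if (net@model == "alpha") {
    .layerBackwardAlphaCpp(gS, cache$E, cache$I, cache$U, cache$S,
                           np$alpha, np$beta, np$uThr, slope, hard)
  } else {
    c(.layerBackwardLifCpp(gS, cache$U, cache$S, np$beta, np$uThr, slope,
                           hard),
      list(gAlpha = NULL))
  }
}

# Full forward + loss + gradients for all trainable groups.
snnGradients <- function(net, current, target, slope = 25, hard = TRUE) {
  nL <- length(net@layerSizes)
  caches <- snnForward(net, current, slope, hard)
  ro <- net@readout
  p <- caches[[nL]]$S
  nt <- nrow(p); ds <- ncol(target)
  rt <- convCausal(p, ro$Ktime)
  rc <- convCausal(p, ro$Kcount)
  z <- ro$gamma * (rt %*% ro$Wtime) + (1 - ro$gamma) * (rc %*% ro$Wcount)
  loss <- mean((z - target)^2)
  gz <- 2 * (z - target) / length(z)
  gWtime <- ro$gamma * crossprod(rt, gz)
  gWcount <- (1 - ro$gamma) * crossprod(rc, gz)
  gP <- convCausalAdj(ro$gamma * gz %*% t(ro$Wtime), ro$Ktime) +
    convCausalAdj((1 - ro$gamma) * gz %*% t(ro$Wcount), ro$Kcount)
  gW <- vector("list", nL - 1L)
  gAlpha <- gBeta <- vector("list", nL)
  gS <- gP
  for (k in rev(seq_len(nL))) {
    bk <- layerBackward(net, k, caches[[k]], gS, slope, hard)
    gAlpha[[k]] <- bk$gAlpha
    gBeta[[k]] <- bk$gBeta
    if (k > 1L) {
      # Iin_k = S_{k-1} %*% W_{k-1}; keep the structural sparsity pattern
      gW[[k - 1L]] <- crossprod(caches[[k - 1L]]$S, bk$gIin) *
        (net@weights[[k - 1L]] != 0)
      gS <- bk$gIin %*% t(net@weights[[k - 1L]])
    }
  }
  list(loss = loss, z = z, caches = caches,
       grads = list(Wtime = gWtime, Wcount = gWcount, W = gW,
                    alpha = gAlpha, beta = gBeta))
}

# Minimal Adam optimizer over a flat list of numeric arrays.
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adamStep <- function(params, grads, state, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * grads[[i]]
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * grads[[i]]^2
    mh <- state$m[[i]] / (1 - b1^state$t)
    vh <- state$v[[i]] / (1 - b2^state$t)
    params[[i]] <- params[[i]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

#' Train a spiking network with backpropagation through time
#'
#' Optimizes the readout weights, the per-neuron membrane decay rates
#' (alpha and beta) and the non-zero synaptic weights to minimize the
#' mean-squared error between the dual count/timing readout and the target
#' stimulus, using a fast-sigmoid surrogate gradient through the spike
#' nonlinearity and the Adam optimizer. When the driving stimulus carries a
#' noiseless target (see [addNoise()]) the loss is computed against that
#' target. Decay rates are projected back into their admissible ranges
#' after every step (rates in (0, 1); alpha > beta for the alpha model).
#'
#' @param net a [SpikeNetwork-class].
#' @param s driving [Stimulus-class].
#' @param epochs number of full-sequence gradient steps (default 200).
#' @param lr Adam learning rate.
#' @param slope fast-sigmoid surrogate slope.
#' @param target optional explicit target matrix (Nt x ds); defaults to the
#'   stimulus' noiseless target.
#' @param trainable character subset of c("readout", "decay", "weights").
#' @param verbose print the loss every 10 epochs.
#' @return list with `net` (trained network) and `lossTrace` (per-epoch
#'   loss, length `epochs` + 1 including the initial loss).
#' @export
trainNetwork <- function(net, s, epochs = 200, lr = 1e-3, slope = 25,
                         target = NULL,
                         trainable = c("readout", "decay", "weights"),
                         verbose = FALSE) {
  enc <- if (net@inputTuning == "quadrant_2d") {
    encodeInput2d(s, net@layerSizes[1L], offsets = net@offsets)
  } else {
    encodeInput1d(s, net@layerSizes[1L], offsets = net@offsets)
  }
  current <- enc$current
  if (is.null(target)) target <- cleanTarget(s)
  target <- as.matrix(target)
  stopIfNot(nrow(target) == nrow(current), "target length must match stimulus")
  nL <- length(net@layerSizes)

  flatten <- function(net) c(
    list(Wtime = net@readout$Wtime, Wcount = net@readout$Wcount),
    stats::setNames(net@weights, paste0("W", seq_len(nL - 1L))),
    stats::setNames(lapply(net@neurons, `[[`, "alpha"), paste0("a", seq_len(nL))),
    stats::setNames(lapply(net@neurons, `[[`, "beta"), paste0("b", seq_len(nL))))
  unflatten <- function(net, p) {
    net@readout$Wtime <- p$Wtime
    net@readout$Wcount <- p$Wcount
    for (k in seq_len(nL - 1L)) net@weights[[k]] <- p[[paste0("W", k)]]
    for (k in seq_len(nL)) {
      a <- p[[paste0("a", k)]]; b <- p[[paste0("b", k)]]
      if (net@model == "alpha") {
        a <- pmin(pmax(a, 1e-3), 0.999)
        b <- pmin(pmax(b, 1e-3), a - 1e-3)   # keep alpha > beta
      } else {
        b <- pmin(pmax(b, 1e-3), 0.999)
      }
      net@neurons[[k]]$alpha <- a
      net@neurons[[k]]$beta <- b
    }
    net
  }

  params <- flatten(net)
  opt <- adamInit(params)
  g0 <- snnGradients(net, current, target, slope)
  lossTrace <- g0$loss
  if (epochs == 0) return(list(net = net, lossTrace = lossTrace))
  gr <- g0$grads
  for (ep in seq_len(epochs)) {
    if (!is.finite(lossTrace[length(lossTrace)])) {
      stop(sprintf("training diverged (non-finite loss at epoch %d)", ep),
           call. = FALSE)
    }
    grads <- stats::setNames(vector("list", length(params)), names(params))
    if ("readout" %in% trainable) {
      grads$Wtime <- gr$Wtime; grads$Wcount <- gr$Wcount
    }
    if ("weights" %in% trainable) {
      for (k in seq_len(nL - 1L)) grads[[paste0("W", k)]] <- gr$W[[k]]
    }
    if ("decay" %in% trainable) {
      for (k in seq_len(nL)) {
        if (net@model == "alpha") grads[[paste0("a", k)]] <- gr$alpha[[k]]
        grads[[paste0("b", k)]] <- gr$beta[[k]]
      }
    }
    stp <- adamStep(params, grads, opt, lr = lr)
    params <- stp$params; opt <- stp$state
    net <- unflatten(net, params)
    params <- flatten(net)                     # pick up projected rates
    gnew <- snnGradients(net, current, target, slope)
    lossTrace <- c(lossTrace, gnew$loss)
    gr <- gnew$grads
    if (verbose && ep %% 10 == 0) {
      message(sprintf("epoch %d: loss %.5f", ep, gnew$loss))
    }
  }
  list(net = net, lossTrace = lossTrace)
}
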
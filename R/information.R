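#' Kraskov-Stogbauer-Grassberger mutual information estimator
#'
#' Type-1 KSG estimate of the mutual information between two (possibly
#' multivariate) continuous variables, in bits. For each point the distance
#' eps_i to its k-th nearest neighbour in the joint space under the
#' Chebyshev (max) norm is found; nx_i and ny_i count the points strictly
#' within eps_i in each marginal space. The estimate is
#' psi(k) + psi(n) - <psi(nx + 1) + psi(ny + 1)> nats, converted to bits.
#' Inputs are perturbed by a tiny deterministic jitter (1e-10 of each
#' column's scale, drawn under `jitterSeed`) to break ties, which matters
#' for discrete-valued inputs such as spike counts. Distances are computed
#' in row chunks, so memory stays O(chunk * n).
#'
#' @param x,y numeric matrices (n x dx, n x dy) or vectors.
#' @param k neighbour count (default 4), k < n.
#' @param jitterSeed seed for the tie-breaking jitter.
#' @param chunk rows per distance chunk.
#' @param minN smallest admissible sample count (default 50; the
#'   single-neuron decomposition relaxes this for conditional estimates on
#'   small count classes).
#' @return list with `value` (bits), `k`, `n`, `method` = "ksg1". Estimator
#'   noise can make the value slightly negative near independence.
#' @export
ksgMI <- function(x, y, k = 4, jitterSeed = 1L, chunk = 256L, minN = 50L) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  stopIfNot(nrow(y) == n, "x and y need the same number of rows")
  stopIfNot(n >= minN, sprintf("need at least %d samples", minN))
  stopIfNot(k < n, "k must be smaller than the sample count")
  degen <- function(m) any(apply(m, 2, function(cl) stats::sd(cl) == 0))
  if (degen(x) || degen(y)) {
    stop("degenerate input: a column is constant", call. = FALSE)
  }
  jit <- function(m, off) {
    withSeed(jitterSeed + off, {
      for (j in seq_len(ncol(m))) {
        sc <- stats::sd(m[, j]); if (!is.finite(sc) || sc == 0) sc <- 1
        m[, j] <- m[, j] + stats::runif(n, -1, 1) * 1e-10 * sc
      }
      m
    })
  }
  x <- jit(x, 0L); y <- jit(y, 1L)
  xy <- cbind(x, y)
  dx <- ncol(x)
  # max-norm distances from rows `idx` to all rows, over columns `cols`
  chebDist <- function(m, idx) {
    d <- abs(outer(m[idx, 1], m[, 1], "-"))
    if (ncol(m) > 1) {
      for (j in 2:ncol(m)) d <- pmax(d, abs(outer(m[idx, j], m[, j], "-")))
    }
    d
  }
  eps <- numeric(n)
  nx <- ny <- numeric(n)
  starts <- seq.int(1L, n, by = chunk)
  for (s0 in starts) {
    idx <- s0:min(n, s0 + chunk - 1L)
    dj <- chebDist(xy, idx)
    dj[cbind(seq_along(idx), idx)] <- Inf        # exclude self
    eps[idx] <- apply(dj, 1, function(r) sort(r, partial = k)[k])
    dxm <- chebDist(x, idx)
    dym <- chebDist(y, idx)
    nx[idx] <- rowSums(dxm < eps[idx]) - 1       # strictly within, minus self
    ny[idx] <- rowSums(dym < eps[idx]) - 1
  }
  val <- (digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))) /
    log(2)
  list(value = val, k = k, n = n, method = "ksg1")
}

#' Single-neuron spike count / spike timing information decomposition
#'
#' Splits the mutual information between a single neuron's windowed
#' response and the stimulus into a spike-count term Im(s, Rc) and a
#' spike-timing term sum_i p(Rc = i) Im(Rt, s | Rc = i): the timing term
#' only counts information beyond what the count already explains, making
#' the decomposition conservative about timing. Windows are non-overlapping
#' of width `T` ms; the stimulus representative of a window is its value at
#' the window start. Count classes with fewer than `minClass` windows are
#' dropped from the timing sum together with their weight (a message
#' reports the dropped probability mass).
#'
#' @param spikes one neuron's binary spike train (vector or one-column
#'   matrix/[SpikeRaster-class]).
#' @param s the [Stimulus-class] (noiseless target used when present) or a
#'   numeric matrix aligned with the spike train.
#' @param T window width in ms (default 50).
#' @param k KSG neighbour count (default 4).
#' @param minClass minimum windows per count class for the conditional MI
#'   (default 2 * (k + 1)).
#' @return list with `countBits`, `timingBits`, `totalBits` (per window),
#'   `countRate`, `timingRate` (bits/s), `classWeights` (p(Rc = i) used),
#'   `droppedMass`.
#' @export
singleNeuronInfo <- function(spikes, s, T = 50, k = 4, minClass = 2 * (k + 1)) {
  sv <- if (is(s, "Stimulus")) cleanTarget(s) else as.matrix(s)
  win <- nonoverlappingWindows(spikes, T)
  nT <- length(win$counts)
  sW <- sv[(seq_len(nT) - 1L) * T + 1L, , drop = FALSE]
  # count information: KSG between (jittered) discrete counts and stimulus
  countBits <- if (stats::sd(win$counts) == 0) {
    0  # a constant count carries no information by construction
  } else {
    max(0, ksgMI(matrix(win$counts, ncol = 1), sW, k = k)$value)
  }
  # timing information: count-weighted conditional MI within count classes
  timingBits <- 0
  dropped <- 0
  cmax <- max(win$counts)
  weights <- numeric(0)
  if (cmax >= 1) {
    for (i in seq_len(cmax)) {
      sel <- win$counts == i
      pI <- mean(sel)
      if (pI == 0) next
      if (sum(sel) < max(minClass, k + 2)) {
        dropped <- dropped + pI
        next
      }
      rt <- win$times[sel, seq_len(i), drop = FALSE]
      sI <- sW[sel, , drop = FALSE]
      # a constant conditional (fixed timings or fixed stimulus within the
      # class) carries no timing information
      constCol <- function(m) any(apply(m, 2, function(cl) stats::sd(cl) == 0))
      cond <- if (constCol(rt) || constCol(sI)) 0 else {
        max(0, ksgMI(rt, sI, k = k, minN = max(minClass, k + 2))$value)
      }
      timingBits <- timingBits + pI * cond
      weights[as.character(i)] <- pI
    }
  }
  if (dropped > 0) {
    message(sprintf("dropped count classes carrying %.3f probability mass",
                    dropped))
  }
  list(countBits = countBits, timingBits = timingBits,
       totalBits = countBits + timingBits,
       countRate = countBits * 1000 / T, timingRate = timingBits * 1000 / T,
       classWeights = weights, droppedMass = dropped)
}

#' Layer-wise single-neuron information table
#'
#' Applies [singleNeuronInfo()] to every neuron of every raster and returns
#' a columnar table.
#'
#' @param rasters named list of [SpikeRaster-class] (as from
#'   [simulateNetwork()]).
#' @param s the [Stimulus-class].
#' @inheritParams singleNeuronInfo
#' @param maxNeurons cap on neurons analysed per layer (subsampled evenly);
#'   `Inf` analyses all.
#' @return data.frame with columns layer, neuron, countBits, timingBits,
#'   countRate, timingRate.
#' @export
layerInfoTable <- function(rasters, s, T = 50, k = 4, maxNeurons = Inf) {
  rows <- list()
  for (r in rasters) {
    sp <- spikeMatrix(r)
    nn <- ncol(sp)
    pick <- if (nn > maxNeurons) {
      unique(round(seq(1, nn, length.out = maxNeurons)))
    } else seq_len(nn)
    for (j in pick) {
      inf <- suppressMessages(singleNeuronInfo(sp[, j], s, T = T, k = k))
      rows[[length(rows) + 1L]] <- data.frame(
        layer = layerLabel(r), neuron = j,
        countBits = inf$countBits, timingBits = inf$timingBits,
        countRate = inf$countRate, timingRate = inf$timingRate)
    }
  }
  do.call(rbind, rows)
}

#' Population mutual-information rate curve
#'
#' Mutual information rate Rinfo = Im(s, sHat) / T between the true
#' stimulus and its decoded estimate, per bin width. By the data-processing
#' inequality this lower-bounds the stimulus information in the binned
#' response itself. Rates are reported in bits/s.
#'
#' @param decoded named list (names = deltaT values) of lists with elements
#'   `predictions` and `truth` (as returned by [decoderTestScore()]).
#' @param T window width in ms.
#' @param k KSG neighbour count.
#' @param layer layer label for the curve.
#' @param seed seed label recorded in the curve rows.
#' @return an [InformationCurve-class] with metric "MIrate".
#' @export
populationMiCurve <- function(decoded, T = 50, k = 4, layer = "layer",
                              seed = 0L) {
  rows <- lapply(names(decoded), function(dt) {
    d <- decoded[[dt]]
    mi <- ksgMI(d$truth, d$predictions, k = k)$value
    data.frame(deltaT = as.numeric(dt), seed = seed,
               value = mi * 1000 / T)
  })
  informationCurve(layer, "MIrate", do.call(rbind, rows))
}
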
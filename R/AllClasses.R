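#' @import methods
NULL

#' Stimulus: a multichannel time-dependent signal
#'
#' A real-valued matrix of `Nt` time points by `ds` channels sampled on a
#' regular grid of step `dt` (ms). Additive components of a compound signal
#' (e.g. the 4 Hz and 20 Hz terms of a sum of sines) are retained in
#' `components` so they can be decoded individually; `clean` optionally holds
#' the noiseless version of a noise-corrupted stimulus, used as the training
#' and decoding target.
#'
#' @slot values numeric matrix (Nt x ds), arbitrary units.
#' @slot dt time step in ms.
#' @slot components named list of numeric matrices (Nt x ds), one per
#'   additive term; possibly empty.
#' @slot clean either `NULL` or the noiseless stimulus matrix (Nt x ds).
#' @slot seed integer seed used for any random draw, or `NA_integer_`.
#'
#' @exportClass Stimulus
setClass("Stimulus",
  representation(
    values = "matrix",
    dt = "numeric",
    components = "list",
    clean = "ANY",
    seed = "integer"
  ),
  prototype(components = list(), clean = NULL, seed = NA_integer_)
)

setValidity("Stimulus", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (length(object@dt) != 1L || object@dt <= 0) {
    msg <- c(msg, "dt must be a single positive number")
  }
  if (!ncol(v) %in% c(1L, 2L)) msg <- c(msg, "ds (ncol of values) must be 1 or 2")
  for (cmp in object@components) {
    if (!identical(dim(cmp), dim(v))) {
      msg <- c(msg, "every component must have the same shape as values")
      break
    }
  }
  if (!is.null(object@clean) && !identical(dim(object@clean), dim(v))) {
    msg <- c(msg, "clean must be NULL or match the shape of values")
  }
  if (length(msg)) msg else TRUE
})

#' SpikeRaster: binary spike trains of one layer
#'
#' Binary matrix (Nt x Nnrn) at 1 ms resolution; entry (t, j) is 1 iff
#' neuron j fired in time step t. At most one spike per neuron per step,
#' which enforces an effective 1 ms refractory floor.
#'
#' @slot spikes binary numeric matrix (Nt x Nnrn).
#' @slot dt time step in ms.
#' @slot label layer label, e.g. "input", "hidden", "output".
#'
#' @exportClass SpikeRaster
setClass("SpikeRaster",
  representation(spikes = "matrix", dt = "numeric", label = "character"),
  prototype(dt = 1, label = "layer")
)

setValidity("SpikeRaster", function(object) {
  s <- object@spikes
  if (!is.numeric(s)) return("spikes must be numeric")
  if (length(s) && !all(s %in% c(0, 1))) return("spikes must be binary (0/1)")
  if (object@dt <= 0) return("dt must be positive")
  TRUE
})

#' SpikeNetwork: a feedforward network of spiking neurons
#'
#' Layer sizes, neuron model ("alpha" or "lif"), per-neuron dynamical
#' parameters, sparse signed inter-layer weights, input-encoding scheme and
#' the dual count/timing readout used during training.
#'
#' @slot layerSizes integer vector (Nin, ..., Nout).
#' @slot model "alpha" or "lif".
#' @slot p connection probability in (0, 1].
#' @slot inputTuning "quadrant_2d" or "direction_1d".
#' @slot neurons list (one per layer) of per-neuron parameter lists:
#'   `alpha`, `beta` (decay rates), `uThr` (threshold); reset potential is 0.
#' @slot weights list of (Npre x Npost) weight matrices, length nLayers - 1.
#' @slot offsets numeric vector of per-neuron input tuning offsets.
#' @slot readout list with `Wtime`, `Wcount` (Nout x ds), `gamma`,
#'   `Ktime`, `Kcount` kernel vectors.
#' @slot normConvention "variance" or "sd": how N(0, v) parameters of the
#'   weight and offset distributions are read.
#' @slot seed integer seed the network was built from.
#'
#' @exportClass SpikeNetwork
setClass("SpikeNetwork",
  representation(
    layerSizes = "integer",
    model = "character",
    p = "numeric",
    inputTuning = "character",
    neurons = "list",
    weights = "list",
    offsets = "numeric",
    readout = "list",
    normConvention = "character",
    seed = "integer"
  )
)

setValidity("SpikeNetwork", function(object) {
  msg <- character()
  if (length(object@layerSizes) < 2L || any(object@layerSizes < 1L)) {
    msg <- c(msg, "layerSizes must be >= 2 positive integers")
  }
  if (!object@model %in% c("alpha", "lif")) msg <- c(msg, "model must be 'alpha' or 'lif'")
  if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must be in (0, 1]")
  if (!object@inputTuning %in% c("quadrant_2d", "direction_1d")) {
    msg <- c(msg, "inputTuning must be 'quadrant_2d' or 'direction_1d'")
  }
  nin <- object@layerSizes[1L]
  if (object@inputTuning == "quadrant_2d" && nin %% 4L != 0L) {
    msg <- c(msg, "quadrant_2d input tuning requires Nin divisible by 4")
  }
  if (object@inputTuning == "direction_1d" && nin %% 2L != 0L) {
    msg <- c(msg, "direction_1d input tuning requires Nin divisible by 2")
  }
  if (length(object@weights) != length(object@layerSizes) - 1L) {
    msg <- c(msg, "need one weight matrix per consecutive layer pair")
  } else {
    for (k in seq_along(object@weights)) {
      d <- dim(object@weights[[k]])
      if (d[1L] != object@layerSizes[k] || d[2L] != object@layerSizes[k + 1L]) {
        msg <- c(msg, sprintf("weights[[%d]] must be %d x %d", k,
                              object@layerSizes[k], object@layerSizes[k + 1L]))
      }
    }
  }
  if (object@model == "alpha") {
    for (np in object@neurons) {
      if (any(np$alpha <= np$beta)) {
        msg <- c(msg, "alpha model requires alpha > beta for every neuron")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' BinnedResponse: decoder-ready binned spike tensor
#'
#' Sliding windows of width `T` ms, each sub-divided into bins of width
#' `deltaT` ms; `tensor` holds spike counts per (sample, neuron, bin).
#' `alignedStimulus` holds the stimulus value at each window start, the
#' quantity the window is used to decode.
#'
#' @slot tensor numeric array (nsamples x nfeatures x nbins).
#' @slot windowMs window width T in ms.
#' @slot deltaT bin width in ms.
#' @slot stride window stride in steps.
#' @slot alignedStimulus numeric matrix (nsamples x ds).
#'
#' @exportClass BinnedResponse
setClass("BinnedResponse",
  representation(
    tensor = "array",
    windowMs = "numeric",
    deltaT = "numeric",
    stride = "integer",
    alignedStimulus = "matrix"
  )
)

setValidity("BinnedResponse", function(object) {
  d <- dim(object@tensor)
  if (length(d) != 3L) return("tensor must be 3-dimensional")
  if (object@windowMs %% object@deltaT != 0) return("T must be divisible by deltaT")
  if (d[3L] != object@windowMs / object@deltaT) return("nbins must equal T / deltaT")
  if (nrow(object@alignedStimulus) != d[1L]) {
    return("alignedStimulus must have one row per sample")
  }
  TRUE
})

#' InformationCurve: association metric as a function of bin width
#'
#' Per-layer mapping from temporal resolution `deltaT` to an association
#' metric (decoding accuracy R^2 or mutual-information rate), replicated
#' across network seeds. The least-squares slope of metric against `deltaT`
#' quantifies the preference for timing over count coding; the accuracy gain
#' is metric(5 ms) - metric(50 ms).
#'
#' @slot layer layer label.
#' @slot metric "R2" or "MIrate".
#' @slot values data.frame with columns deltaT, seed, value.
#'
#' @exportClass InformationCurve
setClass("InformationCurve",
  representation(layer = "character", metric = "character", values = "data.frame")
)

setValidity("InformationCurve", function(object) {
  v <- object@values
  if (!all(c("deltaT", "seed", "value") %in% names(v))) {
    return("values needs columns deltaT, seed, value")
  }
  if (!object@metric %in% c("R2", "MIrate")) return("metric must be 'R2' or 'MIrate'")
  if (object@metric == "R2" && any(v$value > 1 + 1e-9)) return("R2 values cannot exceed 1")
  TRUE
})

setMethod("show", "Stimulus", function(object) {
  cat(sprintf("Stimulus: %d time steps x %d channel(s), dt = %g ms\n",
              nrow(object@values), ncol(object@values), object@dt))
  if (length(object@components)) {
    cat("  components:", paste(names(object@components), collapse = ", "), "\n")
  }
  if (!is.null(object@clean)) cat("  noiseless target retained\n")
})

setMethod("show", "SpikeRaster", function(object) {
  cat(sprintf("SpikeRaster '%s': %d steps x %d neurons, %d spikes\n",
              object@label, nrow(object@spikes), ncol(object@spikes),
              sum(object@spikes)))
})

setMethod("show", "SpikeNetwork", function(object) {
  cat(sprintf("SpikeNetwork (%s): layers %s, p = %g, input tuning %s\n",
              object@model, paste(object@layerSizes, collapse = "-"),
              object@p, object@inputTuning))
})

setMethod("show", "BinnedResponse", function(object) {
  d <- dim(object@tensor)
  cat(sprintf(
    "BinnedResponse: %d samples x %d neurons x %d bins (T = %g ms, dt = %g ms)\n",
    d[1L], d[2L], d[3L], object@windowMs, object@deltaT))
})

setMethod("show", "InformationCurve", function(object) {
  cat(sprintf("InformationCurve [%s, %s]: %d points over deltaT {%s}\n",
              object@layer, object@metric, nrow(object@values),
              paste(sort(unique(object@values$deltaT)), collapse = ", ")))
})
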
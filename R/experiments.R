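#' Decode one layer across bin widths
#'
#' Bins a layer's raster at every requested bin width, fits a decoder per
#' bin width, and returns test-set decoding accuracies (and, optionally,
#' the test predictions for downstream mutual-information estimates).
#'
#' @param raster a [SpikeRaster-class].
#' @param s the [Stimulus-class] driving the simulation (its noiseless
#'   target is decoded when present).
#' @param deltaTs bin widths in ms (divisors of `T`).
#' @param T window width in ms.
#' @param stride window stride in steps.
#' @param target optional explicit target matrix overriding the stimulus.
#' @param keepPredictions also return per-deltaT test predictions.
#' @param ... passed to [fitDecoder()] (architecture, budgets, seed, ...).
#' @return list with `r2` (data.frame deltaT, value) and, if requested,
#'   `decoded` (per-deltaT lists with predictions and truth).
#' @export
decodeLayerCurve <- function(raster, s, deltaTs = c(1, 2, 5, 10, 25, 50),
                             T = 50, stride = 1L, target = NULL,
                             keepPredictions = FALSE, ...) {
  tgt <- if (is.null(target)) {
    if (is(s, "Stimulus")) cleanTarget(s) else as.matrix(s)
  } else as.matrix(target)
  rows <- list(); decoded <- list()
  for (dt in deltaTs) {
    br <- binSpikes(raster, tgt, T = T, deltaT = dt, stride = stride)
    dec <- fitDecoder(br, ...)
    ts <- decoderTestScore(dec, br)
    rows[[length(rows) + 1L]] <- data.frame(deltaT = dt, value = ts$r2)
    if (keepPredictions) decoded[[as.character(dt)]] <- ts
  }
  out <- list(r2 = do.call(rbind, rows))
  if (keepPredictions) out$decoded <- decoded
  out
}

# Build, train and simulate one 3-layer network on a sum-of-sines stimulus.
threeLayerRun <- function(nh, seed, fLow, fHigh, duration, epochs, lr,
                          model, decoderTarget = NULL, nIn = 100,
                          nOut = 100) {
  s <- sumOfSines(fLow, fHigh, duration = duration,
                  seed = childSeed(seed, 1))
  net <- spikeNetwork(c(nIn, nh, nOut), model = model,
                      inputTuning = "quadrant_2d", seed = childSeed(seed, 2))
  tr <- trainNetwork(net, s, epochs = epochs, lr = lr)
  rasters <- simulateNetwork(tr$net, s)
  list(stimulus = s, net = tr$net, lossTrace = tr$lossTrace,
       rasters = rasters)
}

#' Three-layer hidden-size sweep
#'
#' Trains 3-layer networks (Nin = Nout = 100) for every hidden-layer size
#' in `nhGrid` and every seed, then decodes the requested layers across the
#' bin-width grid. Returns per-(Nh, layer, deltaT, seed) accuracies plus
#' slope and accuracy-gain summaries and a one-sided rank-sum comparison of
#' the hidden-layer gains between the smallest (bottleneck) and largest
#' (expansion) Nh.
#'
#' @param nhGrid hidden-layer sizes (default 10, 100, 1000).
#' @param seeds integer seeds, one network per seed.
#' @param fLow,fHigh stimulus component frequencies (Hz).
#' @param duration stimulus duration in ms.
#' @param epochs training epochs.
#' @param lr training learning rate.
#' @param model "alpha" or "lif".
#' @param layers layers to decode.
#' @param deltaTs bin-width grid (ms).
#' @param T window width (ms).
#' @param stride window stride (steps).
#' @param decoderArgs list of arguments for [fitDecoder()].
#' @return list with `curves` (data.frame), `gains`, `slopes`,
#'   `gainTest` (p-value, bottleneck > expansion hidden-layer gain),
#'   `lossTraces`.
#' @export
runThreeLayerSweep <- function(nhGrid = c(10, 100, 1000), seeds = 1:5,
                               fLow = 4, fHigh = 20, duration = 10000,
                               epochs = 200, lr = 1e-3, model = "alpha",
                               layers = c("hidden", "output"),
                               deltaTs = c(1, 2, 5, 10, 25, 50), T = 50,
                               stride = 1L, decoderArgs = list()) {
  curves <- list(); lossTraces <- list()
  for (nh in nhGrid) {
    for (sd in seeds) {
      run <- threeLayerRun(nh, sd, fLow, fHigh, duration, epochs, lr, model)
      lossTraces[[sprintf("Nh%d_seed%d", nh, sd)]] <- run$lossTrace
      for (ly in layers) {
        args <- c(list(raster = run$rasters[[ly]], s = run$stimulus,
                       deltaTs = deltaTs, T = T, stride = stride),
                  decoderArgs,
                  list(seed = childSeed(sd, 3)))
        r2 <- do.call(decodeLayerCurve, args)$r2
        curves[[length(curves) + 1L]] <- data.frame(
          Nh = nh, layer = ly, deltaT = r2$deltaT, seed = sd,
          value = r2$value)
      }
    }
  }
  curves <- do.call(rbind, curves)
  res <- summarizeSweep(curves, nhGrid, T = T)
  res$lossTraces <- lossTraces
  res
}

# Gains, slopes and the bottleneck-vs-expansion rank-sum from a curve table.
summarizeSweep <- function(curves, nhGrid, T = 50) {
  gains <- slopes <- list()
  for (nh in unique(curves$Nh)) {
    for (ly in unique(curves$layer)) {
      sub <- curves[curves$Nh == nh & curves$layer == ly, ]
      if (!nrow(sub)) next
      ic <- informationCurve(ly, "R2", sub)
      if (all(c(5, 50) %in% sub$deltaT)) {
        g <- accuracyGain(ic, perSeed = TRUE)
        gains[[length(gains) + 1L]] <- data.frame(
          Nh = nh, layer = ly, seed = as.integer(names(g)), gain = g)
      }
      if (length(unique(sub$deltaT)) >= 3) {
        sl <- vapply(unique(sub$seed), function(sd) {
          curveSlope(informationCurve(ly, "R2", sub[sub$seed == sd, ]))
        }, numeric(1))
        slopes[[length(slopes) + 1L]] <- data.frame(
          Nh = nh, layer = ly, seed = unique(sub$seed), slope = sl)
      }
    }
  }
  gains <- if (length(gains)) do.call(rbind, gains) else NULL
  slopes <- if (length(slopes)) do.call(rbind, slopes) else NULL
  gainTest <- NA_real_
  if (!is.null(gains) && "hidden" %in% gains$layer && length(nhGrid) >= 2) {
    bn <- gains$gain[gains$Nh == min(nhGrid) & gains$layer == "hidden"]
    ex <- gains$gain[gains$Nh == max(nhGrid) & gains$layer == "hidden"]
    if (length(bn) >= 3 && length(ex) >= 3) {
      # one-sided: expansion gains stochastically smaller than bottleneck
      gainTest <- compareSlopes(ex, bn, alternative = "less")
    }
  }
  list(curves = curves, gains = gains, slopes = slopes, gainTest = gainTest)
}

#' Stimulus-frequency sweep of output-layer slopes
#'
#' For every high-frequency component in `fHighGrid`, trains bottleneck
#' (smallest Nh) and expansion (largest Nh) 3-layer networks across seeds
#' and computes the slope of the output-layer R^2 vs deltaT curve, plus a
#' one-sided rank-sum test that slopes are lower when the output layer is
#' post-synaptic to a convergence (expansion hidden layer).
#'
#' @inheritParams runThreeLayerSweep
#' @param fHighGrid high-frequency components in Hz.
#' @param nhPair c(bottleneck Nh, expansion Nh).
#' @return list with `slopes` (data.frame fHigh, structure, seed, slope)
#'   and `tests` (data.frame fHigh, pValue).
#' @export
runFrequencySweep <- function(fHighGrid = c(10, 20, 30, 40, 50),
                              nhPair = c(10, 1000), seeds = 1:5, fLow = 4,
                              duration = 10000, epochs = 200, lr = 1e-3,
                              model = "alpha",
                              deltaTs = c(1, 2, 5, 10, 25, 50), T = 50,
                              stride = 1L, decoderArgs = list()) {
  stopIfNot(all(fHighGrid > fLow), "fHigh must exceed fLow")
  slopes <- list()
  for (fh in fHighGrid) {
    for (arch in c("bottleneck", "expansion")) {
      nh <- if (arch == "bottleneck") nhPair[1] else nhPair[2]
      for (sd in seeds) {
        run <- threeLayerRun(nh, sd, fLow, fh, duration, epochs, lr, model)
        args <- c(list(raster = run$rasters$output, s = run$stimulus,
                       deltaTs = deltaTs, T = T, stride = stride),
                  decoderArgs, list(seed = childSeed(sd, 3)))
        r2 <- do.call(decodeLayerCurve, args)$r2
        sl <- curveSlope(informationCurve("output", "R2",
                                          cbind(r2, seed = sd)))
        slopes[[length(slopes) + 1L]] <- data.frame(
          fHigh = fh, structure = arch, seed = sd, slope = sl)
      }
    }
  }
  slopes <- do.call(rbind, slopes)
  tests <- do.call(rbind, lapply(unique(slopes$fHigh), function(fh) {
    a <- slopes$slope[slopes$fHigh == fh & slopes$structure == "expansion"]
    b <- slopes$slope[slopes$fHigh == fh & slopes$structure == "bottleneck"]
    data.frame(fHigh = fh, pValue = compareSlopes(a, b, "less"))
  }))
  list(slopes = slopes, tests = tests)
}

#' Five-layer visuomotor pathway model experiments
#'
#' Runs the 5-layer expand/contract/expand/contract network (48 input
#' motion-sensitive neurons, 10 output units by default) in one of two
#' modes. `"sine1hz"`: train on a 1 Hz sinusoid and decompose each layer's
#' single-neuron information into spike-count and spike-timing terms.
#' `"noisy_sos"`: drive with a noise-corrupted 4 + 20 Hz sum of sines,
#' train and decode against the noiseless version, and return per-layer
#' slopes of the R^2 vs deltaT curves.
#'
#' @param mode "sine1hz" or "noisy_sos".
#' @param sizes layer sizes; input and output fixed at 48 and 10 by the
#'   modeled anatomy, intermediates configurable.
#' @param seeds integer seeds.
#' @param duration stimulus duration in ms.
#' @param epochs,lr training settings.
#' @param model "alpha" or "lif".
#' @param noiseSigma SD of the input noise in "noisy_sos" mode.
#' @param T window width (ms).
#' @param deltaTs bin-width grid for "noisy_sos".
#' @param stride window stride for decoding.
#' @param k KSG neighbour count for "sine1hz".
#' @param maxNeurons cap on neurons per layer in the single-neuron
#'   analysis.
#' @param decoderArgs list of arguments for [fitDecoder()].
#' @return for "sine1hz": list with `info` (layer info table with seed
#'   column) and `outputTest` (p-value, output-layer timing > count info).
#'   For "noisy_sos": list with `curves` and `slopes` tables.
#' @export
runFiveLayer <- function(mode = c("sine1hz", "noisy_sos"),
                         sizes = c(48, 960, 24, 240, 10), seeds = 1:5,
                         duration = 10000, epochs = 200, lr = 1e-3,
                         model = "alpha", noiseSigma = 0.5, T = 50,
                         deltaTs = c(1, 2, 5, 10, 25, 50), stride = 1L,
                         k = 4, maxNeurons = 10, decoderArgs = list()) {
  mode <- match.arg(mode)
  stopIfNot(length(sizes) == 5 && sizes[2] > sizes[1] && sizes[3] < sizes[2] &&
              sizes[4] > sizes[3] && sizes[5] < sizes[4],
            "sizes must expand/contract/expand/contract")
  if (mode == "sine1hz") {
    info <- list(); perSeedOut <- list()
    for (sd in seeds) {
      s <- singleSine(1, duration = duration)
      net <- spikeNetwork(sizes, model = model, inputTuning = "direction_1d",
                          seed = childSeed(sd, 2))
      tr <- trainNetwork(net, s, epochs = epochs, lr = lr)
      rasters <- simulateNetwork(tr$net, s)
      tab <- layerInfoTable(rasters, s, T = T, k = k,
                            maxNeurons = maxNeurons)
      tab$seed <- sd
      info[[length(info) + 1L]] <- tab
      outRows <- tab[tab$layer == "output", ]
      perSeedOut[[length(perSeedOut) + 1L]] <- data.frame(
        seed = sd, timing = mean(outRows$timingRate),
        count = mean(outRows$countRate))
    }
    info <- do.call(rbind, info)
    po <- do.call(rbind, perSeedOut)
    outputTest <- if (nrow(po) >= 3) {
      compareSlopes(po$count, po$timing, "less")
    } else NA_real_
    list(info = info, outputSummary = po, outputTest = outputTest)
  } else {
    curves <- list()
    for (sd in seeds) {
      clean <- sumOfSines(4, 20, duration = duration, ds = 1,
                          seed = childSeed(sd, 1))
      noisy <- addNoise(clean, noiseSigma, seed = childSeed(sd, 4))
      net <- spikeNetwork(sizes, model = model, inputTuning = "direction_1d",
                          seed = childSeed(sd, 2))
      tr <- trainNetwork(net, noisy, epochs = epochs, lr = lr)
      rasters <- simulateNetwork(tr$net, noisy)
      for (ly in names(rasters)) {
        args <- c(list(raster = rasters[[ly]], s = noisy, deltaTs = deltaTs,
                       T = T, stride = stride),
                  decoderArgs, list(seed = childSeed(sd, 3)))
        r2 <- do.call(decodeLayerCurve, args)$r2
        curves[[length(curves) + 1L]] <- data.frame(
          layer = ly, deltaT = r2$deltaT, seed = sd, value = r2$value)
      }
    }
    curves <- do.call(rbind, curves)
    slopes <- do.call(rbind, lapply(split(curves,
                                          curves[c("layer", "seed")]),
      function(sub) {
        if (length(unique(sub$deltaT)) < 3) return(NULL)
        data.frame(layer = sub$layer[1], seed = sub$seed[1],
                   slope = curveSlope(informationCurve(sub$layer[1], "R2",
                                                       sub)))
      }))
    rownames(slopes) <- NULL
    list(curves = curves, slopes = slopes)
  }
}

#' Read / run an experiment configuration
#'
#' Experiments are fully described by a YAML configuration with an
#' `experiment` field ("three_layer", "freq_sweep", "five_layer",
#' "entropy_report" or "bin_demo") plus the arguments of the matching
#' `run*` function. All result tables are written as TSV files under
#' `outputDir` when one is given.
#'
#' @param path YAML config path.
#' @return for `readExperimentConfig`, the config list.
#' @export
readExperimentConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopIfNot(!is.null(cfg$experiment), "config needs an 'experiment' field")
  cfg
}

#' @rdname readExperimentConfig
#' @param cfg config list (as from [readExperimentConfig()]).
#' @export
runExperiment <- function(cfg) {
  if (is.character(cfg)) cfg <- readExperimentConfig(cfg)
  outDir <- cfg$outputDir
  cfg$outputDir <- NULL
  kind <- cfg$experiment
  cfg$experiment <- NULL
  res <- switch(kind,
    three_layer = do.call(runThreeLayerSweep, cfg),
    freq_sweep = do.call(runFrequencySweep, cfg),
    five_layer = do.call(runFiveLayer, cfg),
    entropy_report = do.call(entropyBoundTable, cfg),
    bin_demo = {
      rho <- matrix(c(1, 0, 0, 1, 1, 0, 1, 0, 1, 0), ncol = 1)
      lapply(c(8, 4, 2, 1), function(dt) {
        drop(binTensor(binSpikes(rho, matrix(0, 10, 1), T = 8, deltaT = dt)))
      })
    },
    stop(sprintf("unknown experiment '%s'", kind), call. = FALSE))
  if (!is.null(outDir)) writeResultTables(res, outDir)
  res
}

#' Write experiment result tables as TSV
#'
#' @param res result list from a `run*` function.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeResultTables <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.data.frame(res)) res <- list(result = res)
  for (nm in names(res)) {
    x <- res[[nm]]
    if (is.data.frame(x)) {
      utils::write.table(x, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else if (is.numeric(x) && length(x) == 1L) {
      utils::write.table(data.frame(value = x),
                         file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}
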
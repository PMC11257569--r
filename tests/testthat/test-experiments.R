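# Scaled-down smoke runs of the experiment orchestrators: tiny networks,
# short stimuli, ridge decoding and few epochs so the full pipelines run in
# seconds while exercising every stage end to end.

smallDecoder <- list(architecture = "ridge", minSamples = 50)

test_that("three-layer sweep produces schema-valid, reproducible tables", {
  res <- runThreeLayerSweep(
    nhGrid = c(5, 40), seeds = 1:3, duration = 600, epochs = 3, lr = 2e-3,
    deltaTs = c(5, 25, 50), stride = 4L, decoderArgs = smallDecoder)
  expect_named(res, c("curves", "gains", "slopes", "gainTest", "lossTraces"))
  expect_setequal(unique(res$curves$Nh), c(5, 40))
  expect_setequal(unique(res$curves$layer), c("hidden", "output"))
  expect_setequal(unique(res$curves$deltaT), c(5, 25, 50))
  expect_equal(nrow(res$curves), 2 * 3 * 2 * 3)
  expect_true(all(res$curves$value <= 1))
  expect_equal(nrow(res$gains), 2 * 2 * 3)
  expect_true(is.numeric(res$gainTest))
  # provenance: summaries recompute bit-identically from the stored curves
  re <- spikeTempo:::summarizeSweep(res$curves, c(5, 40))
  expect_identical(re$gains, res$gains)
  expect_identical(re$slopes, res$slopes)
  expect_identical(re$gainTest, res$gainTest)
  # reproducibility: same seeds give identical tables
  res2 <- runThreeLayerSweep(
    nhGrid = c(5, 40), seeds = 1:3, duration = 600, epochs = 3, lr = 2e-3,
    deltaTs = c(5, 25, 50), stride = 4L, decoderArgs = smallDecoder)
  expect_identical(res2$curves, res$curves)
})

test_that("frequency sweep rejects degenerate grids and returns slope tables", {
  expect_error(runFrequencySweep(fHighGrid = c(4, 20), fLow = 4),
               "exceed")
  res <- runFrequencySweep(
    fHighGrid = c(20), nhPair = c(5, 40), seeds = 1:3, duration = 600,
    epochs = 2, deltaTs = c(5, 25, 50), stride = 4L,
    decoderArgs = smallDecoder)
  expect_setequal(unique(res$slopes$structure), c("bottleneck", "expansion"))
  expect_equal(nrow(res$slopes), 6)
  expect_true(all(res$tests$pValue >= 0 & res$tests$pValue <= 1))
})

test_that("five-layer runs validate the expand/contract pattern and produce results", {
  expect_error(runFiveLayer("sine1hz", sizes = c(48, 20, 30, 10, 5)),
               "expand/contract")
  res <- runFiveLayer(
    "sine1hz", sizes = c(8, 32, 4, 16, 2), seeds = 1:2, duration = 3000,
    epochs = 2, maxNeurons = 2, k = 3)
  expect_setequal(unique(res$info$layer), c("input", "E1", "B", "E2",
                                            "output"))
  expect_true(all(res$info$countBits >= 0 & res$info$timingBits >= 0))
  expect_equal(nrow(res$outputSummary), 2)
  resN <- runFiveLayer(
    "noisy_sos", sizes = c(8, 32, 4, 16, 2), seeds = 1:2, duration = 600,
    epochs = 2, deltaTs = c(5, 25, 50), stride = 4L,
    decoderArgs = smallDecoder)
  expect_setequal(unique(resN$slopes$layer), c("input", "E1", "B", "E2",
                                               "output"))
  expect_equal(nrow(resN$slopes), 10)
})

test_that("experiments run from a YAML config and write result tables", {
  dir <- withr::local_tempdir()
  cfgPath <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(
    experiment = "three_layer", nhGrid = c(5, 40), seeds = 1:3,
    duration = 600, epochs = 1, deltaTs = c(5, 25, 50), stride = 4,
    decoderArgs = list(architecture = "ridge", minSamples = 50),
    outputDir = file.path(dir, "out")), cfgPath)
  cfg <- readExperimentConfig(cfgPath)
  expect_equal(cfg$experiment, "three_layer")
  res <- runExperiment(cfgPath)
  expect_true(file.exists(file.path(dir, "out", "curves.tsv")))
  back <- read.delim(file.path(dir, "out", "curves.tsv"))
  expect_equal(nrow(back), nrow(res$curves))
  # entropy report and binning demo run from config too
  ent <- runExperiment(list(experiment = "entropy_report", T = 15,
                            tauRef = 5, nNeuronsGrid = c(1, 10)))
  expect_equal(ent$timingRate, c(0.2, 2))
  demo <- runExperiment(list(experiment = "bin_demo"))
  expect_equal(demo[[1]], c(4, 4, 4))
})

test_that("silent layers yield degenerate but structured decoding results", {
  net <- spikeNetwork(c(8, 6, 4), seed = 3)
  net@weights <- lapply(net@weights, function(w) w * 0)
  s <- tinyStim(duration = 600)
  rasters <- simulateNetwork(net, s)
  expect_equal(sum(spikeMatrix(rasters$hidden)), 0)
  wrn <- character()
  out <- withCallingHandlers(
    decodeLayerCurve(rasters$hidden, s, deltaTs = c(25, 50),
                     stride = 4L, architecture = "ridge",
                     minSamples = 50),
    warning = function(w) {
      wrn <<- c(wrn, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  expect_match(wrn, "baseline", all = TRUE)
  expect_length(wrn, 2)
  expect_equal(nrow(out$r2), 2)
  expect_true(all(out$r2$value <= 0 + 1e-9))
})
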
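test_that("quadrant input encoding follows the tuning rule", {
  # s = (1, 1), zero offsets: only the quadrant-1 subpopulation is driven,
  # each receiving the magnitude sqrt(2)
  s <- matrix(c(1, 1), 1, 2)
  enc <- encodeInput2d(s, 8, offsets = rep(0, 8))
  expect_equal(enc$current[1, 1:2], rep(sqrt(2), 2))
  expect_equal(enc$current[1, 3:8], rep(0, 6))
  # origin sits on every quadrant boundary: no one is driven
  enc0 <- encodeInput2d(matrix(0, 1, 2), 8, offsets = rep(0, 8))
  expect_true(all(enc0$current == 0))
  # the four quadrants select the four subpopulations
  pts <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  encQ <- encodeInput2d(pts, 8, offsets = rep(0, 8))
  for (q in 1:4) {
    active <- which(encQ$current[q, ] > 0)
    expect_equal(active, (q - 1) * 2 + 1:2)
  }
  expect_error(encodeInput2d(matrix(0, 1, 1), 8), "2-channel")
  expect_error(encodeInput2d(s, 6), "divisible by 4")
})

test_that("offset draws follow the stated distribution under the variance convention", {
  enc <- encodeInput2d(matrix(0, 1, 2), 10000, offsetVar = 0.1, seed = 2)
  expect_equal(sd(enc$offsets), sqrt(0.1), tolerance = 0.02)
})

test_that("direction input encoding splits the population by sign", {
  enc <- encodeInput1d(matrix(0.5, 1, 1), 6, offsets = rep(0, 6))
  expect_equal(enc$current[1, ], c(0.5, 0.5, 0.5, 0, 0, 0))
  encN <- encodeInput1d(matrix(-0.5, 1, 1), 6, offsets = rep(0, 6))
  expect_equal(encN$current[1, ], c(0, 0, 0, 0.5, 0.5, 0.5))
  expect_true(all(encodeInput1d(matrix(0, 1, 1), 6,
                                offsets = rep(0, 6))$current == 0))
  # alternating sign alternates the active subpopulation
  encA <- encodeInput1d(matrix(c(1, -1, 1, -1), 4, 1), 4,
                        offsets = rep(0, 4))
  expect_equal(encA$current[, 1], c(1, 0, 1, 0))
  expect_equal(encA$current[, 3], c(0, 1, 0, 1))
  expect_error(encodeInput1d(matrix(0, 1, 2), 6), "1-channel")
})

test_that("sparse signed weights have the stated density and variance", {
  w <- makeWeights(100, 1000, p = 1, seed = 5)
  expect_equal(stats::var(as.numeric(w)), 1 / 100, tolerance = 0.01)
  w7 <- makeWeights(200, 500, p = 0.7, seed = 6)
  expect_equal(mean(w7 != 0), 0.7, tolerance = 0.01)
  expect_gt(mean(w7 > 0), 0.3)   # signed: both excitatory and inhibitory
  expect_gt(mean(w7 < 0), 0.3)
  expect_identical(makeWeights(50, 50, 0.7, seed = 1),
                   makeWeights(50, 50, 0.7, seed = 1))
})

test_that("alpha neuron step matches hand iteration and resets on spike", {
  p <- list(alpha = 0.8, beta = 0.7, uThr = 10)
  s1 <- stepAlpha(NULL, 1, p)
  expect_equal(s1$state$iExc, 1)
  expect_equal(s1$state$iInh, -1)
  expect_equal(s1$state$u, 0)           # tau_alpha * (1 - 1)
  s2 <- stepAlpha(s1$state, 0, p)
  ta <- log(0.8) / (log(0.7) - log(0.8)) + 1
  expect_equal(s2$state$u, 0.1 * ta, tolerance = 1e-12)
  # quiescence: zero input, zero state stays silent forever
  st <- NULL
  for (i in 1:20) {
    out <- stepAlpha(st, 0, p)
    st <- out$state
    expect_equal(out$spikes, 0)
  }
  # constant large input produces periodic spiking with reset
  p2 <- list(alpha = 0.8, beta = 0.7, uThr = 0.1)
  st <- NULL; spikes <- numeric(50)
  for (i in 1:50) {
    out <- stepAlpha(st, 1, p2)
    st <- out$state
    spikes[i] <- out$spikes
  }
  expect_gt(sum(spikes), 5)
  expect_true(all(spikes %in% c(0, 1)))
})

test_that("LIF step follows the geometric membrane solution", {
  p <- list(beta = 0.8, uThr = Inf)
  # homogeneous decay from a preset state
  st <- list(u = 1)
  for (i in 1:10) {
    out <- stepLif(st, 0, p)
    st <- out$state
    expect_equal(st$u, 0.8^i, tolerance = 1e-12)
  }
  # constant input converges to the geometric-series fixed point c/(1-beta)
  st <- NULL
  for (i in 1:300) { out <- stepLif(st, 1, p); st <- out$state }
  expect_equal(st$u, 1 / (1 - 0.8), tolerance = 1e-12)
  # hand iteration of threshold crossing: U[1] = 1 (no spike, strict),
  # U[2] = 1.8 (spike), reset, U[3] = 1 again
  p2 <- list(beta = 0.8, uThr = 1)
  o1 <- stepLif(NULL, 1, p2); expect_equal(o1$spikes, 0)
  o2 <- stepLif(o1$state, 1, p2); expect_equal(o2$spikes, 1)
  o3 <- stepLif(o2$state, 1, p2); expect_equal(o3$spikes, 0)
})

test_that("compiled layer simulation agrees with the single-step reference", {
  set.seed(8)
  for (model in c("alpha", "lif")) {
    n <- 5; nt <- 120
    params <- if (model == "alpha") {
      a <- runif(n, 0.7, 0.9)
      list(alpha = a, beta = a - 0.1, uThr = runif(n, 0, 0.5))
    } else {
      list(beta = runif(n, 0.7, 0.9), uThr = runif(n, 0, 1.1))
    }
    current <- matrix(runif(nt * n, 0, 0.6), nt, n)
    fast <- spikeTempo:::runLayer(current, params, model)
    slow <- matrix(0, nt, n)
    st <- NULL
    stepFun <- if (model == "alpha") stepAlpha else stepLif
    for (t in seq_len(nt)) {
      out <- stepFun(st, current[t, ], params)
      st <- out$state
      slow[t, ] <- out$spikes
    }
    expect_identical(fast, slow, info = model)
  }
})

test_that("network construction honours sizes, density and parameter tables", {
  net <- tinyNet(seed = 11)
  expect_identical(layerSizes(net), c(8L, 6L, 4L))
  ws <- networkWeights(net)
  expect_equal(dim(ws[[1]]), c(8, 6))
  expect_equal(dim(ws[[2]]), c(6, 4))
  big <- spikeNetwork(c(400, 100), seed = 3)
  np <- big@neurons[[1]]
  expect_true(all(np$alpha >= 0.7 & np$alpha <= 0.9))
  expect_equal(np$beta, np$alpha - 0.1)            # table rule
  expect_true(all(np$uThr >= 0 & np$uThr <= 0.5))
  lif <- spikeNetwork(c(400, 100), model = "lif", seed = 3)
  expect_true(all(lif@neurons[[1]]$uThr <= 1.1))
  expect_error(spikeNetwork(c(10, 5), p = 0),
               "p must be")
  expect_error(spikeNetwork(c(6, 5), inputTuning = "quadrant_2d"),
               "divisible by 4")
})

test_that("simulation is feedforward, binary and causally structured", {
  net <- tinyNet(seed = 13)
  s <- tinyStim()
  rasters <- simulateNetwork(net, s)
  expect_named(rasters, c("input", "hidden", "output"))
  for (r in rasters) expect_true(all(spikeMatrix(r) %in% c(0, 1)))
  # zero downstream weights silence non-input layers but leave input intact
  net0 <- net
  net0@weights <- lapply(net0@weights, function(w) w * 0)
  rasters0 <- simulateNetwork(net0, s)
  expect_identical(spikeMatrix(rasters0$input), spikeMatrix(rasters$input))
  expect_equal(sum(spikeMatrix(rasters0$hidden)), 0)
  expect_equal(sum(spikeMatrix(rasters0$output)), 0)
  # perturbing downstream weights never changes upstream rasters
  netP <- net
  netP@weights[[2]] <- netP@weights[[2]] * 3
  rastersP <- simulateNetwork(netP, s)
  expect_identical(spikeMatrix(rastersP$input), spikeMatrix(rasters$input))
  expect_identical(spikeMatrix(rastersP$hidden),
                   spikeMatrix(rasters$hidden))
})

test_that("event-list export round-trips spike positions", {
  net <- tinyNet(seed = 17)
  rasters <- simulateNetwork(net, tinyStim())
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEventList(rasters, path)
  df <- read.delim(path)
  expect_equal(nrow(df), sum(vapply(rasters, function(r)
    sum(spikeMatrix(r)), numeric(1))))
  hid <- df[df$layer == "hidden", ]
  sp <- spikeMatrix(rasters$hidden)
  expect_equal(nrow(hid), sum(sp))
  one <- hid[1, ]
  expect_equal(sp[one$time_ms + 1, one$neuron], 1)
})
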
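test_that("R^2 matches a hand-computed oracle and handles edge cases", {
  s <- c(1, 2, 3, 4, 5)
  sHat <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  ssres <- sum((s - sHat)^2)
  sstot <- sum((s - 3)^2)
  expect_equal(rSquared(s, sHat), 1 - ssres / sstot, tolerance = 1e-12)
  expect_equal(rSquared(s, s), 1)
  expect_equal(rSquared(s, rep(mean(s), 5)), 0)
  expect_error(rSquared(rep(1, 5), s), "zero-variance")
})

test_that("recurrent decoder gradients match finite differences", {
  set.seed(1)
  for (arch in c("gru", "lstm")) {
    n <- 7; d <- 3; B <- 4; H <- 5
    X <- array(rnorm(n * d * B), c(n, d, B))
    Y <- matrix(rnorm(n * 2), n, 2)
    p <- spikeTempo:::rnnInitParams(arch, d, H, 2, seed = 5)
    fwd <- spikeTempo:::rnnForward(arch, p, X)
    loss <- mean((fwd$yHat - Y)^2)
    gY <- 2 * (fwd$yHat - Y) / length(Y)
    gp <- spikeTempo:::rnnBackward(arch, p, X, fwd, gY)
    eps <- 1e-6
    for (nm in names(p)) {
      i <- sample(length(p[[nm]]), 1)
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      l2 <- mean((spikeTempo:::rnnForward(arch, p2, X)$yHat - Y)^2)
      fd <- (l2 - loss) / eps
      expect_lt(abs(fd - gp[[nm]][i]) / max(1e-8, abs(fd) + abs(gp[[nm]][i])),
                1e-4, label = paste(arch, nm))
    }
  }
})

test_that("decoders recover a stimulus planted in the features and fail on shuffles", {
  set.seed(7)
  n <- 400
  stim <- matrix(sin(seq_len(n) / 10), ncol = 1)
  tens <- array(rnorm(n * 3 * 2, 0, 0.1), c(n, 3, 2))
  tens[, 1, 1] <- stim[, 1]           # feature 1 literally is the stimulus
  br <- new("BinnedResponse", tensor = tens, windowMs = 2, deltaT = 1,
            stride = 1L, alignedStimulus = stim)
  for (arch in c("ridge", "gru")) {
    dec <- fitDecoder(br, architecture = arch, hidden = 8, lrGrid = 1e-2,
                      epochs = 200, searchBudget = 2, minSamples = 100,
                      seed = 1)
    expect_gt(decoderTestScore(dec, br)$r2, 0.99)
  }
  # shuffled targets: no decodable structure
  shuf <- br
  shuf@alignedStimulus <- stim[sample(n), , drop = FALSE]
  decS <- fitDecoder(shuf, architecture = "ridge", minSamples = 100,
                     seed = 2)
  expect_lt(abs(decoderTestScore(decS, shuf)$r2), 0.05)
})

test_that("the chronological split is disjoint and ordered", {
  sp <- spikeTempo:::chronoSplit(100, 0.2, 0.2)
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  expect_equal(length(intersect(sp$train, sp$validation)), 0)
  expect_equal(sort(c(sp$train, sp$validation, sp$test)), 1:100)
  expect_true(max(sp$train) < min(sp$validation))
  expect_true(max(sp$validation) < min(sp$test))
})

test_that("degenerate all-zero tensors fall back to a baseline predictor", {
  tens <- array(0, c(60, 2, 2))
  stim <- matrix(rnorm(60), ncol = 1)
  br <- new("BinnedResponse", tensor = tens, windowMs = 2, deltaT = 1,
            stride = 1L, alignedStimulus = stim)
  expect_warning(dec <- fitDecoder(br, minSamples = 10), "baseline")
  pred <- predictStimulus(dec, br)
  expect_equal(nrow(pred), 60)
  expect_equal(length(unique(pred[, 1])), 1L)
})

test_that("curve slope equals the closed-form OLS slope", {
  flat <- informationCurve("l", "R2", data.frame(
    deltaT = c(1, 5, 10, 25, 50), seed = 1, value = 0.5))
  expect_equal(curveSlope(flat), 0)
  lin <- informationCurve("l", "R2", data.frame(
    deltaT = c(1, 5, 10, 25, 50), seed = 1,
    value = 1 - 0.002 * c(1, 5, 10, 25, 50)))
  expect_equal(curveSlope(lin), -0.002, tolerance = 1e-12)
  set.seed(9)
  df <- data.frame(deltaT = rep(c(1, 5, 10, 25, 50), 2),
                   seed = rep(1:2, each = 5),
                   value = runif(10, 0, 0.9))
  x <- df$deltaT; y <- df$value
  ols <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(curveSlope(informationCurve("l", "R2", df)), ols,
               tolerance = 1e-12)
})

test_that("accuracy gain uses the 5 ms and 50 ms endpoints per seed", {
  df <- data.frame(deltaT = rep(c(5, 50), 2), seed = rep(1:2, each = 2),
                   value = c(0.9, 0.8, 0.7, 0.7))
  cv <- informationCurve("l", "R2", df)
  expect_equal(accuracyGain(cv), mean(c(0.1, 0)), tolerance = 1e-12)
  expect_equal(unname(accuracyGain(cv, perSeed = TRUE)), c(0.1, 0))
  same <- informationCurve("l", "R2", data.frame(
    deltaT = c(5, 50), seed = 1, value = c(0.6, 0.6)))
  expect_equal(accuracyGain(same), 0)
  expect_error(accuracyGain(informationCurve("l", "R2", data.frame(
    deltaT = c(1, 10), seed = 1, value = c(0.5, 0.5)))), "endpoints")
})

test_that("rank-sum comparison matches exact enumeration", {
  # identical groups: one-sided p near 0.5
  # discreteness of the small-sample permutation null leaves p a bit above
  # one half for fully tied groups
  expect_equal(compareSlopes(1:5 / 10, 1:5 / 10, "less"), 0.5,
               tolerance = 0.2)
  # completely separated, n = 10 each: p equals the exact tail 1/C(20,10)
  a <- seq(0.01, 0.10, by = 0.01)
  b <- seq(1.01, 1.10, by = 0.01)
  expect_equal(compareSlopes(a, b, "less"), 1 / choose(20, 10),
               tolerance = 1e-12)
  # tied data uses the exact permutation fallback and stays in [0, 1]
  p <- compareSlopes(c(1, 1, 2, 2), c(2, 2, 3, 3), "less")
  expect_true(p > 0 && p < 1)
  # oracle: direct enumeration on a tiny tied example
  g1 <- c(1, 2); g2 <- c(2, 3)
  r <- rank(c(g1, g2))
  cmb <- combn(4, 2)
  sums <- colSums(matrix(r[cmb], nrow = 2))
  pOracle <- mean(sums <= sum(r[1:2]))
  g1b <- c(1, 2, 1.5); g2b <- c(2, 3, 2.5)  # need >= 3 per group
  rb <- rank(c(g1b, g2b))
  cmbB <- combn(6, 3)
  pOracleB <- mean(colSums(matrix(rb[cmbB], nrow = 3)) <= sum(rb[1:3]))
  expect_equal(compareSlopes(g1b, g2b, "less"), pOracleB, tolerance = 1e-12)
})

test_that("Bayesian search finds the best of a small candidate grid", {
  # deterministic objective with a unique optimum; the search must find it
  # within a budget smaller than the grid
  grid <- expand.grid(hidden = c(4, 8, 16, 32, 64), lr = c(1, 2, 3))
  evalFun <- function(row) -((log2(row$hidden) - 4)^2 + (row$lr - 2)^2)
  res <- spikeTempo:::bayesOptSearch(evalFun, grid, budget = 10, seed = 1)
  expect_equal(res$best$hidden, 16)
  expect_equal(res$best$lr, 2)
  expect_lte(nrow(res$history), 10)
})
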
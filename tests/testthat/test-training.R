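test_that("readout kernel matches its closed form on the open support", {
  k10 <- readoutKernel(10, 0.1)
  expect_length(k10, 10)
  expect_equal(k10[5], 1)                        # peak at deltaT/2
  expect_equal(k10[3], exp(-(3 - 5)^2 * 0.1))    # exp(-0.4)
  expect_equal(k10[10], 0)                       # outside (0, deltaT)
  k70 <- readoutKernel(70, 0.1)
  expect_length(k70, 70)
  expect_equal(which.max(k70), 35)
  expect_error(readoutKernel(10, sigma = 0), "positive")
})

test_that("dual readout mixes timing and count convolutions as specified", {
  ro <- list(Wtime = matrix(1, 1, 1), Wcount = matrix(1, 1, 1),
             gamma = 0.5, Ktime = readoutKernel(10, 0.1),
             Kcount = readoutKernel(70, 0.1))
  # silent output -> identically zero readout
  z0 <- readoutSignal(matrix(0, 200, 1), ro)
  expect_true(all(z0 == 0))
  # single spike: impulse response is the mixed kernel pair
  p <- matrix(0, 200, 1); p[50, 1] <- 1
  z <- readoutSignal(p, ro)
  expect_equal(z[49, 1], 0)
  expect_equal(z[50 + 4, 1],
               0.5 * readoutKernel(10, 0.1)[5] +
                 0.5 * readoutKernel(70, 0.1)[5])
  expect_equal(z[130, 1], 0)                     # beyond both supports
  # gamma = 1 -> pure timing readout with 10 ms support
  ro1 <- ro; ro1$gamma <- 1
  z1 <- readoutSignal(p, ro1)
  expect_equal(sum(z1[60:200, 1] != 0), 0)
  expect_equal(z1[50:59, 1], readoutKernel(10, 0.1))
})

test_that("MSE loss agrees with a direct loop oracle", {
  s <- tinyStim(duration = 250)
  z <- stimValues(s)
  expect_equal(lossMse(z, s), 0)
  expect_equal(lossMse(z + 1, s), 1)
  set.seed(4)
  zr <- matrix(rnorm(length(z)), nrow(z), ncol(z))
  sv <- stimValues(s)
  acc <- 0
  for (t in seq_len(nrow(sv))) for (ch in seq_len(ncol(sv))) {
    acc <- acc + (zr[t, ch] - sv[t, ch])^2
  }
  expect_equal(lossMse(zr, s), acc / length(sv), tolerance = 1e-12)
})

test_that("surrogate BPTT gradients match finite differences in relaxed mode", {
  for (model in c("alpha", "lif")) {
    net <- tinyNet(model = model, seed = 7)
    s <- tinyStim()
    enc <- encodeInput2d(s, 8, offsets = net@offsets)
    target <- stimValues(s)
    g <- spikeTempo:::snnGradients(net, enc$current, target, slope = 25,
                                   hard = FALSE)
    lossOf <- function(n2) spikeTempo:::snnGradients(
      n2, enc$current, target, slope = 25, hard = FALSE)$loss
    eps <- 1e-6
    relErr <- function(fd, an) abs(fd - an) / max(1e-8, abs(fd) + abs(an))
    n2 <- net; n2@readout$Wtime[2, 1] <- n2@readout$Wtime[2, 1] + eps
    expect_lt(relErr((lossOf(n2) - g$loss) / eps, g$grads$Wtime[2, 1]), 1e-4)
    idx <- which(net@weights[[1]] != 0, arr.ind = TRUE)[1, ]
    n2 <- net
    n2@weights[[1]][idx[1], idx[2]] <- n2@weights[[1]][idx[1], idx[2]] + eps
    expect_lt(relErr((lossOf(n2) - g$loss) / eps,
                     g$grads$W[[1]][idx[1], idx[2]]), 1e-3)
    n2 <- net; n2@neurons[[2]]$beta[1] <- n2@neurons[[2]]$beta[1] + eps
    expect_lt(relErr((lossOf(n2) - g$loss) / eps, g$grads$beta[[2]][1]),
              5e-3)
    if (model == "alpha") {
      n2 <- net; n2@neurons[[2]]$alpha[2] <- n2@neurons[[2]]$alpha[2] + eps
      expect_lt(relErr((lossOf(n2) - g$loss) / eps, g$grads$alpha[[2]][2]),
                5e-3)
    }
  }
})

test_that("gradient flows to every trainable group on nontrivial input", {
  net <- tinyNet(seed = 19)
  s <- tinyStim()
  enc <- encodeInput2d(s, 8, offsets = net@offsets)
  g <- spikeTempo:::snnGradients(net, enc$current, stimValues(s))
  expect_gt(sum(abs(g$grads$Wtime)), 0)
  expect_gt(sum(abs(g$grads$Wcount)), 0)
  for (k in 1:2) expect_gt(sum(abs(g$grads$W[[k]])), 0)
  for (k in 1:3) {
    expect_gt(sum(abs(g$grads$alpha[[k]])), 0)
    expect_gt(sum(abs(g$grads$beta[[k]])), 0)
  }
  # structural zeros in the weight matrices stay zero in the gradient
  expect_true(all(g$grads$W[[1]][net@weights[[1]] == 0] == 0))
})

test_that("training reduces the loss, is deterministic, and no-ops at zero epochs", {
  s <- sumOfSines(4, 20, duration = 500, seed = 23)
  net <- spikeNetwork(c(20, 10, 12), seed = 29)
  same <- trainNetwork(net, s, epochs = 0)
  expect_identical(same$net, net)
  expect_length(same$lossTrace, 1)
  tr1 <- trainNetwork(net, s, epochs = 15, lr = 2e-3)
  tr2 <- trainNetwork(net, s, epochs = 15, lr = 2e-3)
  expect_identical(tr1$lossTrace, tr2$lossTrace)
  expect_lt(tail(tr1$lossTrace, 1), tr1$lossTrace[1])
  # trained decay rates remain in their admissible ranges
  for (k in 1:3) {
    np <- tr1$net@neurons[[k]]
    expect_true(all(np$alpha > np$beta))
    expect_true(all(np$beta > 0 & np$alpha < 1))
  }
})

test_that("training against a noiseless target uses that target", {
  clean <- sumOfSines(4, 20, duration = 500, ds = 1, seed = 31)
  noisy <- addNoise(clean, 0.5, seed = 32)
  net <- spikeNetwork(c(20, 10, 12), inputTuning = "direction_1d",
                      seed = 33)
  tr <- trainNetwork(net, noisy, epochs = 2, lr = 1e-3)
  # loss evaluated against the clean target, not the noisy drive
  enc <- encodeInput1d(noisy, 20, offsets = net@offsets)
  g <- spikeTempo:::snnGradients(tr$net, enc$current, cleanTarget(noisy))
  expect_equal(tail(tr$lossTrace, 1), g$loss, tolerance = 1e-10)
})
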
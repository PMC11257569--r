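#' SpikeDecoder: a fitted stimulus decoder
#'
#' Result of [fitDecoder()]: a sequence decoder (LSTM or GRU over the bin
#' axis) or a ridge regressor mapping binned population responses to
#' stimulus estimates, together with its chronological train/validation/test
#' split and goodness-of-fit scores.
#'
#' @slot architecture "lstm", "gru" or "ridge".
#' @slot params fitted parameter list.
#' @slot featureStats per-neuron standardization statistics from the
#'   training split.
#' @slot config list of fitting settings actually used.
#' @slot scores named numeric vector (train/validation/test R^2).
#' @slot split list of train/validation/test sample indices.
#'
#' @exportClass SpikeDecoder
setClass("SpikeDecoder",
  representation(architecture = "character", params = "list",
                 featureStats = "list", config = "list",
                 scores = "numeric", split = "list"))

setMethod("show", "SpikeDecoder", function(object) {
  cat(sprintf("SpikeDecoder (%s): R2 train %.3f / val %.3f / test %.3f\n",
              object@architecture, object@scores["train"],
              object@scores["validation"], object@scores["test"]))
})

#' Coefficient of determination
#'
#' R^2 = 1 - SSres/SStot per channel, averaged over channels. Can be
#' negative for a worse-than-mean predictor; errors on zero-variance truth.
#'
#' @param s true stimulus matrix (n x ds) or vector.
#' @param sHat estimate of the same shape.
#' @return scalar <= 1.
#' @export
rSquared <- function(s, sHat) {
  s <- as.matrix(s); sHat <- as.matrix(sHat)
  stopIfNot(all(dim(s) == dim(sHat)), "shapes of s and sHat differ")
  r2 <- vapply(seq_len(ncol(s)), function(ch) {
    sst <- sum((s[, ch] - mean(s[, ch]))^2)
    if (sst == 0) stop("zero-variance truth: R^2 undefined", call. = FALSE)
    1 - sum((s[, ch] - sHat[, ch])^2) / sst
  }, numeric(1))
  mean(r2)
}

# ---- chronological split and standardization -------------------------------

chronoSplit <- function(n, valFraction = 0.2, testFraction = 0.2) {
  nTest <- max(1L, floor(n * testFraction))
  nVal <- max(1L, floor(n * valFraction))
  nTrain <- n - nVal - nTest
  stopIfNot(nTrain >= 1L, "too few samples for a train/val/test split")
  list(train = seq_len(nTrain),
       validation = seq.int(nTrain + 1L, nTrain + nVal),
       test = seq.int(nTrain + nVal + 1L, n))
}

# Per-neuron z-scoring: mean/sd over training samples and bins.
featureStandardize <- function(tens, trainIdx, stats = NULL) {
  nf <- dim(tens)[2]
  if (is.null(stats)) {
    mu <- sdv <- numeric(nf)
    for (j in seq_len(nf)) {
      x <- tens[trainIdx, j, ]
      mu[j] <- mean(x)
      sdv[j] <- stats::sd(as.numeric(x))
      if (!is.finite(sdv[j]) || sdv[j] == 0) sdv[j] <- 1
    }
    stats <- list(mu = mu, sd = sdv)
  }
  for (j in seq_len(nf)) tens[, j, ] <- (tens[, j, ] - stats$mu[j]) / stats$sd[j]
  list(tensor = tens, stats = stats)
}

# ---- ridge decoder ---------------------------------------------------------

# Ridge on flattened (nfeatures x nbins) windows; dual (kernel) form when
# the feature count exceeds the sample count.
ridgeFit <- function(X, Y, lambda) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  if (p <= n) {
    B <- solve(crossprod(Xc) + lambda * diag(p), crossprod(Xc, Yc))
  } else {
    A <- tcrossprod(Xc)
    diag(A) <- diag(A) + lambda
    B <- crossprod(Xc, solve(A, Yc))
  }
  list(B = B, xm = xm, ym = ym)
}

ridgePredict <- function(fit, X) {
  sweep(X, 2, fit$xm) %*% fit$B + matrix(fit$ym, nrow(X), length(fit$ym),
                                         byrow = TRUE)
}

# ---- recurrent sequence decoders (GRU / LSTM) ------------------------------
# Hand-written full-batch implementations; the sequence axis is the bin
# axis, so decoding depends on the specific spike sequence within the
# response window. Hidden state after the last bin feeds a linear output.

rnnInitParams <- function(arch, d, H, dOut, seed) {
  withSeed(seed, {
    g <- function(r, c, scale) matrix(stats::rnorm(r * c, 0, scale), r, c)
    sx <- sqrt(1 / d); sh <- sqrt(1 / H)
    if (arch == "gru") {
      list(Wxz = g(d, H, sx), Whz = g(H, H, sh), bz = numeric(H),
           Wxr = g(d, H, sx), Whr = g(H, H, sh), br = numeric(H),
           Wxh = g(d, H, sx), Whh = g(H, H, sh), bh = numeric(H),
           Wout = g(H, dOut, sh), bout = numeric(dOut))
    } else {
      list(Wxi = g(d, H, sx), Whi = g(H, H, sh), bi = numeric(H),
           Wxf = g(d, H, sx), Whf = g(H, H, sh), bf = rep(1, H),
           Wxo = g(d, H, sx), Who = g(H, H, sh), bo = numeric(H),
           Wxg = g(d, H, sx), Whg = g(H, H, sh), bg = numeric(H),
           Wout = g(H, dOut, sh), bout = numeric(dOut))
    }
  })
}

sigm <- function(x) 1 / (1 + exp(-x))
addb <- function(M, b) sweep(M, 2, b, "+")

rnnForward <- function(arch, p, X) {
  # X: n x d x B (samples x features x bins)
  n <- dim(X)[1]; B <- dim(X)[3]
  H <- nrow(p$Wout)
  h <- matrix(0, n, H)
  cache <- vector("list", B)
  if (arch == "lstm") cst <- matrix(0, n, H)
  for (b in seq_len(B)) {
    x <- X[, , b, drop = FALSE]; dim(x) <- dim(X)[1:2]
    if (arch == "gru") {
      z <- sigm(addb(x %*% p$Wxz + h %*% p$Whz, p$bz))
      r <- sigm(addb(x %*% p$Wxr + h %*% p$Whr, p$br))
      hh <- tanh(addb(x %*% p$Wxh + (r * h) %*% p$Whh, p$bh))
      hNew <- (1 - z) * h + z * hh
      cache[[b]] <- list(x = x, hPrev = h, z = z, r = r, hh = hh)
      h <- hNew
    } else {
      i <- sigm(addb(x %*% p$Wxi + h %*% p$Whi, p$bi))
      f <- sigm(addb(x %*% p$Wxf + h %*% p$Whf, p$bf))
      o <- sigm(addb(x %*% p$Wxo + h %*% p$Who, p$bo))
      g <- tanh(addb(x %*% p$Wxg + h %*% p$Whg, p$bg))
      cNew <- f * cst + i * g
      tc <- tanh(cNew)
      cache[[b]] <- list(x = x, hPrev = h, cPrev = cst, i = i, f = f, o = o,
                         g = g, tc = tc)
      cst <- cNew
      h <- o * tc
    }
  }
  yHat <- addb(h %*% p$Wout, p$bout)
  list(yHat = yHat, h = h, cache = cache)
}

rnnBackward <- function(arch, p, X, fwd, gY) {
  B <- dim(X)[3]
  gp <- lapply(p, function(q) q * 0)
  gp$Wout <- crossprod(fwd$h, gY)
  gp$bout <- colSums(gY)
  gh <- gY %*% t(p$Wout)
  if (arch == "lstm") gc <- fwd$h * 0
  for (b in rev(seq_len(B))) {
    cc <- fwd$cache[[b]]
    if (arch == "gru") {
      z <- cc$z; r <- cc$r; hh <- cc$hh; h0 <- cc$hPrev; x <- cc$x
      gz <- gh * (hh - h0) * z * (1 - z)
      ghh <- gh * z * (1 - hh^2)
      gr <- (ghh %*% t(p$Whh)) * h0 * r * (1 - r)
      gp$Wxz <- gp$Wxz + crossprod(x, gz); gp$bz <- gp$bz + colSums(gz)
      gp$Whz <- gp$Whz + crossprod(h0, gz)
      gp$Wxr <- gp$Wxr + crossprod(x, gr); gp$br <- gp$br + colSums(gr)
      gp$Whr <- gp$Whr + crossprod(h0, gr)
      gp$Wxh <- gp$Wxh + crossprod(x, ghh); gp$bh <- gp$bh + colSums(ghh)
      gp$Whh <- gp$Whh + crossprod(r * h0, ghh)
      gh <- gh * (1 - z) + gz %*% t(p$Whz) + gr %*% t(p$Whr) +
        (ghh %*% t(p$Whh)) * r
    } else {
      i <- cc$i; f <- cc$f; o <- cc$o; g <- cc$g; tc <- cc$tc
      h0 <- cc$hPrev; c0 <- cc$cPrev; x <- cc$x
      go <- gh * tc * o * (1 - o)
      gc <- gc + gh * o * (1 - tc^2)
      gi <- gc * g * i * (1 - i)
      gf <- gc * c0 * f * (1 - f)
      gg <- gc * i * (1 - g^2)
      gp$Wxi <- gp$Wxi + crossprod(x, gi); gp$bi <- gp$bi + colSums(gi)
      gp$Whi <- gp$Whi + crossprod(h0, gi)
      gp$Wxf <- gp$Wxf + crossprod(x, gf); gp$bf <- gp$bf + colSums(gf)
      gp$Whf <- gp$Whf + crossprod(h0, gf)
      gp$Wxo <- gp$Wxo + crossprod(x, go); gp$bo <- gp$bo + colSums(go)
      gp$Who <- gp$Who + crossprod(h0, go)
      gp$Wxg <- gp$Wxg + crossprod(x, gg); gp$bg <- gp$bg + colSums(gg)
      gp$Whg <- gp$Whg + crossprod(h0, gg)
      gh <- gi %*% t(p$Whi) + gf %*% t(p$Whf) + go %*% t(p$Who) +
        gg %*% t(p$Whg)
      gc <- gc * f
    }
  }
  gp
}

rnnTrain <- function(arch, Xtr, Ytr, Xval, Yval, hidden, epochs, lr,
                     patience = 10, seed = NA_integer_) {
  p <- rnnInitParams(arch, dim(Xtr)[2], hidden, ncol(Ytr), seed)
  opt <- adamInit(p)
  best <- list(loss = Inf, params = p)
  wait <- 0
  for (ep in seq_len(epochs)) {
    fwd <- rnnForward(arch, p, Xtr)
    gY <- 2 * (fwd$yHat - Ytr) / length(Ytr)
    gp <- rnnBackward(arch, p, Xtr, fwd, gY)
    stp <- adamStep(p, gp, opt, lr = lr)
    p <- stp$params; opt <- stp$state
    vl <- mean((rnnForward(arch, p, Xval)$yHat - Yval)^2)
    if (vl < best$loss - 1e-8) {
      best <- list(loss = vl, params = p); wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  best$params
}

# ---- Bayesian hyperparameter selection -------------------------------------

# Small Gaussian-process expected-improvement search over a discrete
# candidate grid (columns = numeric hyperparameters, standardized
# internally). Deterministic given the seed.
bayesOptSearch <- function(evalFun, grid, budget = 20, nInit = 3,
                           seed = NA_integer_) {
  m <- nrow(grid)
  budget <- min(budget, m)
  X <- scale(as.matrix(grid))
  X[is.nan(X)] <- 0
  tried <- withSeed(seed, sample(m, min(nInit, budget)))
  y <- vapply(tried, function(i) evalFun(grid[i, , drop = FALSE]), numeric(1))
  rbf <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    exp(-pmax(d2, 0) / 2)
  }
  while (length(tried) < budget) {
    rest <- setdiff(seq_len(m), tried)
    Kt <- rbf(X[tried, , drop = FALSE], X[tried, , drop = FALSE])
    diag(Kt) <- diag(Kt) + 1e-4
    Ks <- rbf(X[rest, , drop = FALSE], X[tried, , drop = FALSE])
    ym <- mean(y); ys <- stats::sd(y); if (!is.finite(ys) || ys == 0) ys <- 1
    a <- solve(Kt, (y - ym) / ys)
    mu <- as.numeric(Ks %*% a) * ys + ym
    v <- pmax(1 - rowSums((Ks %*% solve(Kt)) * Ks), 1e-8)
    s <- sqrt(v) * ys
    # expected improvement over the best (largest) score so far
    imp <- mu - max(y)
    zz <- imp / s
    ei <- imp * stats::pnorm(zz) + s * stats::dnorm(zz)
    nxt <- rest[which.max(ei)]
    tried <- c(tried, nxt)
    y <- c(y, evalFun(grid[nxt, , drop = FALSE]))
  }
  list(best = grid[tried[which.max(y)], , drop = FALSE],
       history = cbind(grid[tried, , drop = FALSE], score = y))
}

# ---- fitDecoder ------------------------------------------------------------

#' Fit a stimulus decoder to a binned response
#'
#' Trains a sequence decoder (LSTM or GRU whose sequence axis is the bin
#' axis of the window) or a ridge regressor to reconstruct the stimulus
#' value at each window start from the binned population response. Samples
#' are split chronologically into disjoint train/validation/test blocks;
#' features are z-scored per neuron on the training split. Decoder
#' hyperparameters (hidden size and learning rate, or the ridge penalty)
#' are selected by maximizing validation R^2 with a Gaussian-process
#' expected-improvement search over a discrete grid.
#'
#' @param br a [BinnedResponse-class].
#' @param architecture "lstm" (default), "gru" or "ridge".
#' @param hidden hidden sizes searched (sequence decoders).
#' @param lrGrid learning rates searched (sequence decoders).
#' @param lambdaGrid ridge penalties searched.
#' @param epochs maximum training epochs per candidate.
#' @param valFraction,testFraction chronological split fractions.
#' @param searchBudget maximum hyperparameter evaluations.
#' @param minSamples minimum number of windows required.
#' @param seed integer seed (initialization and search).
#' @return a [SpikeDecoder-class].
#' @export
fitDecoder <- function(br, architecture = c("lstm", "gru", "ridge"),
                       hidden = c(16, 32, 64), lrGrid = c(1e-3, 1e-2),
                       lambdaGrid = 10^seq(-2, 3), epochs = 100,
                       valFraction = 0.2, testFraction = 0.2,
                       searchBudget = 20, minSamples = 500,
                       seed = NA_integer_) {
  architecture <- match.arg(architecture)
  tens <- binTensor(br)
  Y <- alignedStimulus(br)
  n <- dim(tens)[1]
  if (n < minSamples) {
    warning(sprintf("only %d samples (< %d); decoder fit may be unstable",
                    n, minSamples))
  }
  split <- chronoSplit(n, valFraction, testFraction)
  if (all(tens == 0)) {
    warning("all-zero response tensor; returning baseline (mean) predictor")
    ym <- colMeans(Y[split$train, , drop = FALSE])
    sc <- c(train = 0, validation = 0, test = 0)
    return(new("SpikeDecoder", architecture = "baseline",
               params = list(ym = ym), featureStats = list(),
               config = list(), scores = sc, split = split))
  }
  std <- featureStandardize(tens, split$train)
  tens <- std$tensor
  X2d <- function(idx) {
    m <- tens[idx, , , drop = FALSE]
    dim(m) <- c(length(idx), dim(tens)[2] * dim(tens)[3])
    m
  }
  scoreOf <- function(pred, idx) rSquared(Y[idx, , drop = FALSE], pred)

  if (architecture == "ridge") {
    Xtr <- X2d(split$train); Xv <- X2d(split$validation)
    evalFun <- function(row) {
      fit <- ridgeFit(Xtr, Y[split$train, , drop = FALSE], row$lambda)
      scoreOf(ridgePredict(fit, Xv), split$validation)
    }
    bo <- bayesOptSearch(evalFun, data.frame(lambda = lambdaGrid),
                         budget = min(searchBudget, length(lambdaGrid)),
                         seed = seed)
    fit <- ridgeFit(X2d(c(split$train, split$validation)),
                    Y[c(split$train, split$validation), , drop = FALSE],
                    bo$best$lambda)
    params <- fit
    config <- list(lambda = bo$best$lambda, search = bo$history)
  } else {
    Xtr <- tens[split$train, , , drop = FALSE]
    Xv <- tens[split$validation, , , drop = FALSE]
    Ytr <- Y[split$train, , drop = FALSE]
    Yv <- Y[split$validation, , drop = FALSE]
    grid <- expand.grid(hidden = hidden, lr = lrGrid)
    evalFun <- function(row) {
      pp <- rnnTrain(architecture, Xtr, Ytr, Xv, Yv, row$hidden, epochs,
                     row$lr, seed = childSeed(seed, row$hidden))
      scoreOf(rnnForward(architecture, pp, Xv)$yHat, split$validation)
    }
    bo <- bayesOptSearch(evalFun, grid, budget = min(searchBudget, nrow(grid)),
                         seed = seed)
    params <- rnnTrain(architecture, Xtr, Ytr, Xv, Yv, bo$best$hidden,
                       epochs, bo$best$lr,
                       seed = childSeed(seed, bo$best$hidden))
    config <- list(hidden = bo$best$hidden, lr = bo$best$lr,
                   epochs = epochs, search = bo$history)
  }
  dec <- new("SpikeDecoder", architecture = architecture, params = params,
             featureStats = std$stats, config = config,
             scores = c(train = 0, validation = 0, test = 0), split = split)
  pr <- function(idx) predictIdx(dec, tens, idx)
  dec@scores <- c(train = scoreOf(pr(split$train), split$train),
                  validation = scoreOf(pr(split$validation), split$validation),
                  test = scoreOf(pr(split$test), split$test))
  dec
}

predictIdx <- function(dec, tens, idx) {
  if (dec@architecture == "ridge") {
    m <- tens[idx, , , drop = FALSE]
    dim(m) <- c(length(idx), dim(tens)[2] * dim(tens)[3])
    ridgePredict(dec@params, m)
  } else if (dec@architecture == "baseline") {
    matrix(dec@params$ym, length(idx), length(dec@params$ym), byrow = TRUE)
  } else {
    rnnForward(dec@architecture, dec@params,
               tens[idx, , , drop = FALSE])$yHat
  }
}

#' Predict the stimulus from a binned response
#'
#' @param dec a fitted [SpikeDecoder-class].
#' @param br a [BinnedResponse-class] with matching features and bins.
#' @param idx sample indices to predict (default all).
#' @return numeric matrix (length(idx) x ds).
#' @export
predictStimulus <- function(dec, br, idx = NULL) {
  tens <- binTensor(br)
  if (dec@architecture != "baseline") {
    tens <- featureStandardize(tens, NULL, dec@featureStats)$tensor
  }
  if (is.null(idx)) idx <- seq_len(dim(tens)[1])
  predictIdx(dec, tens, idx)
}

#' Test-set R^2 and predictions of a decoder
#'
#' @param dec a fitted [SpikeDecoder-class].
#' @param br the [BinnedResponse-class] it was fitted to.
#' @return list with `r2`, `predictions`, `truth` (test split).
#' @export
decoderTestScore <- function(dec, br) {
  idx <- dec@split$test
  pred <- predictStimulus(dec, br, idx)
  truth <- alignedStimulus(br)[idx, , drop = FALSE]
  list(r2 = rSquared(truth, pred), predictions = pred, truth = truth)
}

# ---- curve summaries -------------------------------------------------------

#' Least-squares slope of an information curve
#'
#' Ordinary least-squares slope of the association metric against the bin
#' width deltaT (per ms), pooled over seeds. Negative slopes indicate a
#' preference for temporal over count coding.
#'
#' @param curve an [InformationCurve-class] (>= 3 distinct deltaT values).
#' @return slope in metric units per ms.
#' @export
curveSlope <- function(curve) {
  v <- curveValues(curve)
  stopIfNot(length(unique(v$deltaT)) >= 3, "need >= 3 deltaT points")
  unname(stats::coef(stats::lm(value ~ deltaT, data = v))[2])
}

#' Accuracy gain of the temporal code over the count code
#'
#' metric(deltaT = `fine`) - metric(deltaT = `coarse`), computed per seed
#' (both endpoints must exist for the seed).
#'
#' @param curve an [InformationCurve-class].
#' @param fine,coarse endpoint bin widths in ms (defaults 5 and 50).
#' @param perSeed return the per-seed gains instead of their mean.
#' @return mean gain, or a named per-seed vector.
#' @export
accuracyGain <- function(curve, fine = 5, coarse = 50, perSeed = FALSE) {
  v <- curveValues(curve)
  stopIfNot(all(c(fine, coarse) %in% v$deltaT),
            "curve lacks the requested deltaT endpoints")
  a <- v[v$deltaT == fine, ]
  b <- v[v$deltaT == coarse, ]
  seeds <- intersect(a$seed, b$seed)
  g <- vapply(seeds, function(sd) {
    mean(a$value[a$seed == sd]) - mean(b$value[b$seed == sd])
  }, numeric(1))
  names(g) <- seeds
  if (perSeed) g else mean(g)
}

#' One-sided rank-sum comparison of slope (or gain) distributions
#'
#' Wilcoxon rank-sum (Mann-Whitney) test of `groupA` against `groupB` with
#' the caller-specified direction. With ties and small samples, an exact
#' permutation enumeration of the rank-sum statistic is used instead of the
#' normal approximation.
#'
#' @param groupA,groupB numeric vectors (>= 3 values each).
#' @param alternative "less" (default; A stochastically smaller than B) or
#'   "greater".
#' @return one-sided p-value.
#' @export
compareSlopes <- function(groupA, groupB, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  stopIfNot(length(groupA) >= 3 && length(groupB) >= 3,
            "need >= 3 values per group")
  hasTies <- any(duplicated(c(groupA, groupB)))
  nTot <- length(groupA) + length(groupB)
  if (hasTies && nTot <= 20) {
    # exact permutation distribution of the rank-sum of group A
    r <- rank(c(groupA, groupB))
    obs <- sum(r[seq_along(groupA)])
    combs <- utils::combn(nTot, length(groupA))
    sums <- colSums(matrix(r[combs], nrow = length(groupA)))
    if (alternative == "less") mean(sums <= obs) else mean(sums >= obs)
  } else {
    suppressWarnings(
      stats::wilcox.test(groupA, groupB, alternative = alternative,
                         exact = !hasTies)$p.value)
  }
}

#' Build an information curve from per-(deltaT, seed) values
#'
#' @param layer layer label.
#' @param metric "R2" or "MIrate".
#' @param df data.frame with columns deltaT, seed, value.
#' @return an [InformationCurve-class].
#' @export
informationCurve <- function(layer, metric, df) {
  new("InformationCurve", layer = layer, metric = metric,
      values = df[, c("deltaT", "seed", "value")])
}
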
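# Independent scalar reimplementations of both loss terms act as oracles for
# the vectorized versions, alongside the analytic hand cases.

naiveCountLoss <- function(p, E) {
  mu <- 0; s2 <- 1e-6
  for (pk in p) { mu <- mu + pk; s2 <- s2 + pk * (1 - pk) }
  0.5 * (E - mu)^2 / s2 + log(sqrt(2 * pi) * sqrt(s2))
}

naiveLocLoss <- function(out, gt) {
  H <- nrow(out@p); W <- ncol(out@p)
  sp <- sum(out@p)
  tot <- 0
  for (e in seq_len(nrow(gt))) {
    mix <- 0
    for (i in seq_len(H)) for (j in seq_len(W)) {
      w <- out@p[i, j] / sp
      muR <- (i - 1) + out@dRow[i, j]
      muC <- (j - 1) + out@dCol[i, j]
      dens <- exp(-0.5 * (((gt$row[e] - muR) / out@sigmaRow[i, j])^2 +
                          ((gt$col[e] - muC) / out@sigmaCol[i, j])^2 +
                          ((gt$brightness[e] - out@I[i, j]) / out@sigmaI[i, j])^2)) /
        ((2 * pi)^1.5 * out@sigmaRow[i, j] * out@sigmaCol[i, j] * out@sigmaI[i, j])
      mix <- mix + w * dens
    }
    tot <- tot - log(mix)
  }
  tot / nrow(gt)
}

randomOutput <- function(H, W) {
  m <- function(lo, hi) matrix(runif(H * W, lo, hi), H, W)
  new("DecodeOutput", p = m(0.01, 1), dRow = m(-0.49, 0.49),
      dCol = m(-0.49, 0.49), I = m(0.2, 2), sigmaRow = m(0.2, 2),
      sigmaCol = m(0.2, 2), sigmaI = m(0.2, 2), B = m(0, 1), sigmaB = m(0.5, 1))
}

test_that("count loss reproduces the Gaussian count likelihood", {
  # K = 4, p = 0.5, E = 2: mu = 2, sigma2 = 1 -> loss = log(sqrt(2 pi))
  expect_equal(countLoss(rep(0.5, 4), 2), log(sqrt(2 * pi)), tolerance = 1e-6)
  # saturated probabilities with exact count: the floored minimum, finite and
  # below any perturbed configuration
  pSat <- c(1, 1, 0, 0)
  lSat <- countLoss(pSat, 2)
  expect_true(is.finite(lSat))
  expect_equal(lSat, log(sqrt(2 * pi * 1e-6)), tolerance = 1e-9)
  expect_lt(lSat, countLoss(c(0.95, 1, 0.05, 0), 2))
  # stationarity at mu = E: symmetric difference quotient vanishes
  f <- function(eps) countLoss(c(0.5 + eps, 0.5 - eps, 0.5, 0.5), 2)
  expect_lt(abs((f(1e-4) - f(-1e-4)) / 2e-4), 1e-6)
})

test_that("count loss matches a naive loop on fuzzed instances", {
  set.seed(12)
  for (i in 1:300) {
    K <- sample(1:64, 1)
    p <- runif(K)
    E <- sample(0:6, 1)
    expect_equal(countLoss(p, E), naiveCountLoss(p, E), tolerance = 1e-9)
  }
})

test_that("localization loss reproduces the single-component hand case", {
  out <- constOutput(1, 1, p = 1, dRow = 0.3, dCol = -0.2)
  gt <- data.frame(row = 0.3, col = -0.2, brightness = 1)
  # unit covariance at the GT: -log((2 pi)^{-3/2}) = 1.5 log(2 pi)
  expect_equal(localizationLoss(out, gt), 1.5 * log(2 * pi), tolerance = 1e-6)
})

test_that("zero-probability components drop out of the mixture", {
  out <- constOutput(1, 2, p = c(1, 0), dRow = 0, dCol = 0)
  gt <- data.frame(row = 0, col = 0, brightness = 1)
  single <- constOutput(1, 1, p = 1)
  expect_equal(localizationLoss(out, gt), localizationLoss(single, gt),
               tolerance = 1e-9)
  allZero <- constOutput(1, 2, p = 0)
  expect_error(localizationLoss(allZero, gt), "zero")
})

test_that("log-sum-exp evaluation matches direct summation", {
  set.seed(13)
  for (i in 1:100) {
    H <- sample(2:4, 1); W <- sample(2:4, 1)
    out <- randomOutput(H, W)
    E <- sample(1:3, 1)
    gt <- data.frame(row = runif(E, 0, H - 1), col = runif(E, 0, W - 1),
                     brightness = runif(E, 0.3, 1.5))
    expect_equal(localizationLoss(out, gt), naiveLocLoss(out, gt),
                 tolerance = 1e-8)
  }
})

test_that("total loss assembles count and localization terms", {
  out <- constOutput(2, 2, p = 0.5)
  # empty frame: count term only
  empty <- data.frame(row = numeric(), col = numeric(),
                      brightness = numeric())
  expect_equal(totalLoss(out, empty), countLoss(out@p, 0))
  # perfect single-bubble prediction: floored count term + 3-D normalizer
  o1 <- constOutput(1, 1, p = 1)
  g1 <- data.frame(row = 0, col = 0, brightness = 1)
  expect_equal(totalLoss(o1, g1),
               countLoss(matrix(1, 1, 1), 1) + 1.5 * log(2 * pi),
               tolerance = 1e-9)
  # finite on fuzzed inputs
  set.seed(14)
  for (i in 1:1000) {
    H <- sample(2:5, 1); W <- sample(2:5, 1)
    o <- randomOutput(H, W)
    E <- sample(0:4, 1)
    g <- data.frame(row = runif(E, -1, H), col = runif(E, -1, W),
                    brightness = runif(E, 0, 3))
    expect_true(is.finite(totalLoss(o, g)))
  }
})

test_that("localization loss is minimized at the ground truth position", {
  # single-component mixture: gradient w.r.t. the offset vanishes at the GT
  gt <- data.frame(row = 0.2, col = -0.1, brightness = 1)
  lossAt <- function(dr, dc) {
    out <- constOutput(1, 1, p = 1, dRow = dr, dCol = dc)
    localizationLoss(out, gt)
  }
  e <- 1e-5
  gRow <- (lossAt(0.2 + e, -0.1) - lossAt(0.2 - e, -0.1)) / (2 * e)
  gCol <- (lossAt(0.2, -0.1 + e) - lossAt(0.2, -0.1 - e)) / (2 * e)
  expect_lt(abs(gRow), 1e-6)
  expect_lt(abs(gCol), 1e-6)
  expect_gt(lossAt(0.4, -0.1), lossAt(0.2, -0.1))
})

test_that("analytic loss gradients agree with numerical differentiation", {
  set.seed(15)
  H <- 3; W <- 3
  out <- randomOutput(H, W)
  gt <- data.frame(row = c(0.5, 1.7), col = c(1.1, 2.2),
                   brightness = c(1, 0.7))
  lc <- ulmloc:::locLossCore(out, gt)
  fields <- c("p", "dRow", "dCol", "I", "sigmaRow", "sigmaCol", "sigmaI")
  for (f in fields) {
    for (k in sample(H * W, 3)) {
      e <- 1e-6
      up <- out; slot(up, f)[k] <- slot(up, f)[k] + e
      dn <- out; slot(dn, f)[k] <- slot(dn, f)[k] - e
      gNum <- (localizationLoss(up, gt) - localizationLoss(dn, gt)) / (2 * e)
      expect_equal(unname(lc$grad[[f]][k]), gNum, tolerance = 1e-4)
    }
  }
  # count-loss gradient
  p <- matrix(runif(9), 3, 3)
  gAna <- ulmloc:::countLossGrad(p, 4)
  for (k in sample(9, 4)) {
    e <- 1e-7
    up <- p; up[k] <- up[k] + e
    dn <- p; dn[k] <- dn[k] - e
    expect_equal(gAna[k], (countLoss(up, 4) - countLoss(dn, 4)) / (2 * e),
                 tolerance = 1e-5)
  }
})
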
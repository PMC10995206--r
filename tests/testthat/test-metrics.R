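test_that("matching handles the identity and gated hand cases", {
  pts <- data.frame(row = c(1, 5, 9), col = c(2, 4, 8))
  m <- matchLocalizations(pts, pts, radius = 5)
  expect_equal(m$TP, 3L)
  expect_equal(m$FP, 0L)
  expect_equal(m$FN, 0L)
  expect_true(all(m$tpPairs$distance == 0))

  # one prediction 6 px from the only GT with radius 5: FP and FN
  m2 <- matchLocalizations(data.frame(row = 0, col = 0),
                           data.frame(row = 6, col = 0), radius = 5)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(0L, 1L, 1L))
})

test_that("matching equals brute-force optimum on random small instances", {
  set.seed(51)
  for (i in 1:100) {
    nP <- sample(0:8, 1); nG <- sample(0:8, 1)
    pred <- data.frame(row = runif(nP, 0, 10), col = runif(nP, 0, 10))
    gt <- data.frame(row = runif(nG, 0, 10), col = runif(nG, 0, 10))
    radius <- runif(1, 1, 4)
    m <- matchLocalizations(pred, gt, radius)
    ref <- bruteMatch(pred, gt, radius)
    expect_equal(m$TP, max(ref$TP, 0L))
    if (m$TP > 0)
      expect_equal(sum(m$tpPairs$distance), ref$cost, tolerance = 1e-9)
    # bookkeeping invariants
    expect_equal(m$TP + m$FN, nG)
    expect_equal(m$TP + m$FP, nP)
    expect_true(all(m$tpPairs$distance <= radius + 1e-12))
    # swapping pred/gt swaps FP and FN, TP fixed
    ms <- matchLocalizations(gt, pred, radius)
    expect_equal(ms$TP, m$TP)
    expect_equal(ms$FP, m$FN)
    expect_equal(ms$FN, m$FP)
  }
})

test_that("accuracy, miss rate and localization error match hand values", {
  # TP = 3, FP = 1 -> accuracy 0.75; TP = 3, FN = 1 -> miss 0.25
  pred <- data.frame(row = c(0, 10, 20, 50), col = c(0, 0, 0, 0))
  gt <- data.frame(row = c(0, 10, 20, 90), col = c(0, 0, 0, 0))
  m <- matchLocalizations(pred, gt, radius = 5)
  expect_equal(detectionAccuracy(m), 0.75)
  expect_equal(missRate(m), 0.25)
  expect_equal(localizationError(m, pred, gt), 0)

  # a single pair offset by (3, 4): sqrt((9 + 16) / 2)
  p1 <- data.frame(row = 3, col = 4)
  g1 <- data.frame(row = 0, col = 0)
  m1 <- matchLocalizations(p1, g1, radius = 6)
  expect_equal(localizationError(m1, p1, g1), sqrt(25 / 2), tolerance = 1e-9)
  expect_equal(localizationError(m1, p1, g1), 3.5355, tolerance = 1e-4)

  # two pairs offset by (1,0) and (0,1): sqrt(((1/2) + (1/2)) / 2)
  p2 <- data.frame(row = c(1, 10), col = c(0, 11))
  g2 <- data.frame(row = c(0, 10), col = c(0, 10))
  m2 <- matchLocalizations(p2, g2, radius = 3)
  expect_equal(localizationError(m2, p2, g2), sqrt(0.5), tolerance = 1e-9)

  # degenerate cases are flagged NaN
  e <- data.frame(row = numeric(), col = numeric())
  expect_true(is.nan(detectionAccuracy(matchLocalizations(e, g1, 5))))
  expect_true(is.nan(missRate(matchLocalizations(p1, e, 5))))
  expect_true(is.nan(localizationError(matchLocalizations(p1, g1, 1), p1, g1)))
})

test_that("the printed error formula equals a scalar loop reimplementation", {
  set.seed(52)
  pred <- data.frame(row = runif(20, 0, 30), col = runif(20, 0, 30))
  gt <- data.frame(row = pred$row + rnorm(20, 0, 0.5),
                   col = pred$col + rnorm(20, 0, 0.5))
  m <- matchLocalizations(pred, gt, radius = 3)
  acc <- 0
  for (k in seq_len(m$TP)) {
    i <- m$tpPairs$pred[k]; j <- m$tpPairs$gt[k]
    acc <- acc + ((pred$row[i] - gt$row[j])^2 + (pred$col[i] - gt$col[j])^2) / 2
  }
  expect_equal(localizationError(m, pred, gt), sqrt(acc / m$TP),
               tolerance = 1e-12)
})

test_that("vessel filling counts only the covered ground-truth pixels", {
  gt <- matrix(0, 10, 10); gt[3:6, 3:6] <- 1
  expect_equal(vesselFilling(gt, gt), 100)
  half <- gt; half[5:6, ] <- 0
  expect_equal(vesselFilling(half, gt), 50)
  # reconstruction outside the GT does not change VF
  extra <- half; extra[9:10, 9:10] <- 1
  expect_equal(vesselFilling(extra, gt), 50)
  expect_error(vesselFilling(gt, matrix(0, 10, 10)), "empty")
})

test_that("the benchmark sweep scores oracle and ablated localizers", {
  cfg <- imagingConfig(fovFine = c(48L, 48L))
  bank <- smallBank(3, side = 11L)
  concs <- c(0.05, 0.15)
  seed <- 61
  # oracle localizer: replays the ground truth of the same simulation
  oracleFor <- function(ci) {
    sim <- simulateSequence(cfg, bank, NULL, 20, concs[ci],
                            seed = deriveSeed(seed, paste0("bench", ci)))
    sim$gt
  }
  ci <- 0
  oracle <- function(stack) {
    ci <<- ci + 1
    oracleFor(ci)[, c("frame", "row", "col")]
  }
  tab <- benchmarkSweep(oracle, cfg, bank, NULL, concs, nFrames = 20,
                        seed = seed)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$accuracy_mean, c(1, 1))
  expect_equal(tab$miss_mean, c(0, 0))
  expect_equal(tab$error_mean, c(0, 0))

  # dropping every second bubble halves the recall
  ci <- 0
  half <- function(stack) {
    ci <<- ci + 1
    g <- oracleFor(ci)
    g[seq(1, nrow(g), by = 2), c("frame", "row", "col")]
  }
  ci <- 0
  tabH <- benchmarkSweep(half, cfg, bank, NULL, concs, nFrames = 20,
                         seed = seed)
  expect_true(all(abs(tabH$miss_mean - 0.5) < 0.1))
  expect_equal(tabH$accuracy_mean, c(1, 1))
})

test_that("the 18-step concentration sweep matches the benchmark protocol", {
  concs <- seq(0.02, 0.37, by = 0.02)
  expect_length(concs, 18L)
  cfg <- imagingConfig(fovFine = c(100L, 100L), centerFrequency = 20e6)
  # 0.32 lambda expressed on the 12.3 um fine grid
  expect_equal(matchRadiusPx(cfg), 0.32 * 77 / 12.3, tolerance = 1e-12)
})
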
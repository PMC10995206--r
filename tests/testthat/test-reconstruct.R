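test_that("density accumulation conserves total mass", {
  cfg <- benchConfig()
  # 100 points at one location collapse into a single pixel of value 100
  tr <- data.frame(track = 1L, frame = 0:99, row = 40.2, col = 40.2)
  dens <- accumulateDensity(tr, cfg)
  expect_equal(sum(dens), 100)
  expect_equal(max(dens), 100)
  # arbitrary input: total mass equals number of points
  set.seed(71)
  tr2 <- data.frame(track = rep(1:5, each = 20), frame = rep(0:19, 5),
                    row = runif(100, 0, 79), col = runif(100, 0, 79))
  expect_equal(sum(accumulateDensity(tr2, cfg)), 100)
})

test_that("a diagonal track rasterizes into distinct pixels", {
  cfg <- benchConfig()
  # 45-degree track stepping 2 fine px (24.6 um) per frame; lambda/5 grid is
  # 15.4 um so successive points land in distinct pixels
  tr <- data.frame(track = 1L, frame = 0:9, row = 10 + 2 * (0:9),
                   col = 10 + 2 * (0:9))
  dens <- accumulateDensity(tr, cfg)
  expect_equal(sum(dens > 0), 10L)
  expect_equal(sum(dens), 10)
})

test_that("directional maps sign by axial motion and cancel", {
  cfg <- benchConfig()
  up <- data.frame(track = 1L, frame = 0:9, row = 50 - (0:9), col = 20)
  dup <- directionalMap(up, cfg)
  expect_true(all(dup[dup != 0] > 0))  # toward transducer = positive
  down <- data.frame(track = 2L, frame = 0:9, row = 41 + (0:9), col = 20)
  ddown <- directionalMap(down, cfg)
  expect_true(all(ddown[ddown != 0] < 0))
  # flipping the axial axis flips the sign
  flip <- up; flip$row <- cfg@fovFine[1] - 1 - flip$row
  dflip <- directionalMap(flip, cfg)
  expect_true(all(dflip[dflip != 0] < 0))
  # equal opposing traffic through the same pixels cancels
  both <- rbind(up, transform(up, track = 3L, row = rev(row)))
  dboth <- directionalMap(both, cfg)
  expect_true(all(dboth == 0))
})

test_that("count series tally distinct tracks per pixel and window", {
  cfg <- benchConfig()
  # one track crossing one pixel inside the third one-second window
  tr <- data.frame(track = 1L, frame = 2300:2304, row = 40.1, col = 40.1)
  s <- mbCountSeries(tr, cfg, windowS = 1, nFrames = 5000)
  g <- toReconGrid(40.1, 40.1, cfg)
  series <- s[g$row + 1, g$col + 1, ]
  expect_equal(series, c(0, 0, 1, 0, 0))
  # lingering for 5 frames still counts once (distinct tracks)
  expect_equal(max(s), 1)
  # each track touches at least one pixel-window
  set.seed(72)
  tr2 <- data.frame(track = rep(1:4, each = 10), frame = rep(0:9, 4),
                    row = runif(40, 0, 79), col = runif(40, 0, 79))
  s2 <- mbCountSeries(tr2, cfg, windowS = 1, nFrames = 1000)
  expect_gte(sum(s2), 4)
})

test_that("activation maps recover exact correlations and flag flat pixels", {
  pat <- stimulationPattern(nCycles = 3)
  A <- pat$A
  series <- rbind(2 * A + 1,      # r = +1
                  -A + 5,          # r = -1
                  rep(3, length(A)))  # flat -> r = 0 with flag
  am <- activationMap(series, pat)
  expect_equal(as.numeric(am$r), c(1, -1, 0))
  expect_equal(as.logical(am$activated), c(TRUE, FALSE, FALSE))
  expect_equal(as.logical(am$flat), c(FALSE, FALSE, TRUE))
  # transition seconds are excluded from the mask
  expect_equal(sum(pat$mask), 3 * 60)
  expect_length(A, 3 * 70)
})

test_that("independent noise series are almost never called activated", {
  set.seed(73)
  pat <- stimulationPattern(nCycles = 15)
  noise <- matrix(rnorm(1000 * length(pat$A)), 1000)
  am <- activationMap(noise, pat)
  expect_lt(mean(abs(am$r)), 0.1)
  expect_lt(mean(am$activated), 0.02)
})

test_that("doubling the window leaves block-constant correlations unchanged", {
  pat <- stimulationPattern(nCycles = 4)
  set.seed(74)
  base <- 5 + 3 * pat$A + rnorm(length(pat$A) / 2)[rep(seq_len(length(pat$A) / 2), each = 2)]
  # 2-second blocks: halving the sampling keeps r for block-constant signals
  r1 <- activationMap(matrix(base, 1), pat)$r[1, 1]
  half <- base[seq(1, length(base), by = 2)]
  patH <- list(A = pat$A[seq(1, length(pat$A), by = 2)],
               mask = pat$mask[seq(1, length(pat$A), by = 2)])
  r2 <- activationMap(matrix(half, 1), patH)$r[1, 1]
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("activated pixel counting is strict and monotone in threshold", {
  r <- matrix(0.3, 10, 10)
  expect_equal(activatedPixelCount(r), 100L)
  expect_equal(activatedPixelCount(matrix(0.2, 10, 10)), 0L)  # strict >
  set.seed(75)
  rr <- matrix(runif(100, -1, 1), 10)
  counts <- vapply(c(0, 0.2, 0.5, 0.8), function(t)
    activatedPixelCount(rr, threshold = t), numeric(1))
  expect_true(all(diff(counts) <= 0))
  roi <- matrix(FALSE, 10, 10); roi[1:2, 1:2] <- TRUE
  expect_lte(activatedPixelCount(rr, roi), 4)
})

test_that("modulated vessels activate and null vessels stay silent", {
  pat <- stimulationPattern(nCycles = 15)
  hits <- matrix(0, 100, 2)
  for (s in 1:100) {
    sim <- simulateFulmSeries(pat, nModulated = 2, nNull = 2,
                              baselineRate = 5, stimGain = 2, seed = 1000 + s)
    am <- activationMap(sim$series, pat)
    hits[s, 1] <- mean(am$activated[sim$modulated])
    hits[s, 2] <- mean(am$activated[!sim$modulated])
  }
  expect_gte(mean(hits[, 1]), 0.95)
  expect_lte(mean(hits[, 2]), 0.05)
})
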
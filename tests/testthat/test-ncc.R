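test_that("correlation map hits 1 at a perfect match and is affine-invariant", {
  set.seed(21)
  tp <- templatePatch(makeGaussianTemplate(2, 2, side = 11))
  fr <- matrix(0, 60, 60)
  fr[26:36, 26:36] <- tp
  m <- nccMap(fr, tp)
  expect_equal(max(m), 1, tolerance = 1e-9)
  expect_equal(as.integer(which(m == max(m), arr.ind = TRUE)), c(31L, 31L))
  # positive affine transform leaves the map unchanged
  m2 <- nccMap(2 * fr + 5, tp)
  expect_lt(max(abs(m - m2)[m > -1]), 1e-9)
  # anti-correlation at the paste location of a negated template
  frNeg <- matrix(0, 60, 60)
  frNeg[26:36, 26:36] <- -tp
  m3 <- nccMap(frNeg, tp)
  expect_equal(min(m3), -1, tolerance = 1e-9)
  expect_equal(m3[31, 31], -1, tolerance = 1e-9)
  # borders carry the fill value
  expect_equal(m[1, 1], -1)
  expect_error(nccMap(matrix(0, 5, 5), tp), "smaller")
})

test_that("peak search suppresses neighbours and requires strict maxima", {
  m <- matrix(0, 20, 20)
  m[10, 10] <- 0.9
  m[10, 12] <- 0.8   # distance 2 < minDistance 3: suppressed
  pk <- findPeaks(m, threshold = 0.5, minDistance = 3L)
  expect_equal(nrow(pk), 1L)
  expect_equal(as.integer(pk[1, ]), c(9L, 9L))  # 0-based
  # a uniform map has no strict local maxima
  expect_equal(nrow(findPeaks(matrix(0.7, 10, 10), 0.5, 3L)), 0L)
})

test_that("well-separated peaks are all recovered (brute-force count)", {
  set.seed(22)
  m <- matrix(0, 100, 100)
  rs <- seq(5, 89, by = 12); cs <- seq(5, 89, by = 12)
  pos <- expand.grid(r = rs, c = cs)[1:50, ]
  for (i in 1:50) m[pos$r[i], pos$c[i]] <- runif(1, 0.7, 1)
  pk <- findPeaks(m, threshold = 0.6, minDistance = 3L)
  expect_equal(nrow(pk), 50L)
  expect_setequal(paste(pk[, 1], pk[, 2]), paste(pos$r - 1, pos$c - 1))
})

test_that("sub-pixel refinement is exact on symmetric peaks and clamps", {
  m <- matrix(0, 11, 11)
  m[6, 6] <- 1
  m[5, 6] <- m[7, 6] <- m[6, 5] <- m[6, 7] <- 0.5
  ref <- subpixelRefine(m, rbind(c(5L, 5L)), "paraboloid")
  expect_equal(ref$row, 5)
  expect_equal(ref$col, 5)
  expect_true(ref$refined)
  # border peak returned unrefined with the flag cleared
  refB <- subpixelRefine(m, rbind(c(0L, 0L)), "paraboloid")
  expect_false(refB$refined)
  # pathological neighbourhood: clamped to +/- 0.5
  bad <- matrix(c(0, 0, 0, 0, 0.1, 0.100001, 0, 0, 0), 3, byrow = TRUE)
  refC <- subpixelRefine(bad, rbind(c(1L, 1L)), "paraboloid")
  expect_lte(abs(refC$row - 1), 0.5)
  expect_lte(abs(refC$col - 1), 0.5)
})

test_that("isolated noise-free bubbles localize within 0.15 fine px", {
  cfg <- benchConfig()
  bank <- smallBank(1)
  set.seed(23)
  errs <- vapply(1:40, function(i) {
    pos <- c(runif(1, 30, 50), runif(1, 30, 50))
    st <- data.frame(id = 1L, row = pos[1], col = pos[2], dirRow = 1,
                     dirCol = 0, speed = 5, brightness = 1, lifetime = 20L,
                     age = 0L, tmplIdx = 1L)
    fine <- renderFrame(st, bank, cfg)$fine
    m <- nccMap(fine, templatePatch(getTemplate(bank, 1)))
    pk <- findPeaks(m, 0.5, 3L)
    ref <- subpixelRefine(m, pk[1, , drop = FALSE], "paraboloid")
    sqrt((ref$row - pos[1])^2 + (ref$col - pos[2])^2)
  }, numeric(1))
  expect_lt(max(errs), 0.15)
})

test_that("NCC localization RMSE stays below 0.25 fine px (200 positions)", {
  cfg <- benchConfig()
  bank <- smallBank(1)
  set.seed(24)
  sq <- vapply(1:200, function(i) {
    pos <- c(runif(1, 20, 60), runif(1, 20, 60))
    st <- data.frame(id = 1L, row = pos[1], col = pos[2], dirRow = 1,
                     dirCol = 0, speed = 5, brightness = runif(1, 0.5, 1.5),
                     lifetime = 20L, age = 0L, tmplIdx = 1L)
    fine <- renderFrame(st, bank, cfg)$fine
    stck <- frameStack(array(fine, c(1, dim(fine))), cfg, "fine")
    det <- nccLocalize(stck, getTemplate(bank, 1), nccThreshold = 0.5)
    (det$row[1] - pos[1])^2 + (det$col[1] - pos[2])^2
  }, numeric(1))
  expect_lt(sqrt(mean(sq)), 0.25)
})

test_that("detection count is non-increasing in the NCC threshold", {
  cfg <- benchConfig()
  bank <- smallBank(3)
  sim <- simulateSequence(cfg, bank, inputNoise(cfg), 5, 0.15, seed = 25)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th)
    nrow(nccLocalize(sim$stack, nccThreshold = th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})
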
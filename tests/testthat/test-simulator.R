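test_that("population counts are Poisson in concentration times FOV area", {
  cfg <- imagingConfig(fovFine = c(100L, 100L))
  # FOV area: (100 * 12.3 um / 77 um)^2 = 255.17 lambda^2
  expect_equal(fovAreaLambda2(cfg), (100 * 12.3 / 77)^2, tolerance = 1e-12)
  lambdaMean <- 0.37 * fovAreaLambda2(cfg)
  expect_equal(lambdaMean, 94.41, tolerance = 1e-3)
  set.seed(5)
  counts <- vapply(1:1000, function(i)
    nrow(initPopulation(cfg, 0.37)), numeric(1))
  se <- sqrt(lambdaMean / 1000)
  expect_lt(abs(mean(counts) - lambdaMean), 3 * se)
})

test_that("near-zero concentration yields mostly empty frames", {
  cfg <- imagingConfig(fovFine = c(100L, 100L))
  concEps <- 1 / fovAreaLambda2(cfg)  # Poisson mean 1 -> P(0) = 1/e = 0.368
  set.seed(6)
  empties <- mean(vapply(1:1000, function(i)
    nrow(initPopulation(cfg, concEps)) == 0, logical(1)))
  expect_gte(empties, 0.35 - 3 * sqrt(0.368 * 0.632 / 1000))
})

test_that("population draws are deterministic for a fixed seed", {
  cfg <- benchConfig()
  p1 <- initPopulation(cfg, 0.1, seed = 9)
  p2 <- initPopulation(cfg, 0.1, seed = 9)
  expect_identical(p1, p2)
  s1 <- simulateSequence(cfg, smallBank(), inputNoise(cfg), 5, 0.1, seed = 4)
  s2 <- simulateSequence(cfg, smallBank(), inputNoise(cfg), 5, 0.1, seed = 4)
  expect_identical(stackData(s1$stack), stackData(s2$stack))
  expect_identical(s1$gt, s2$gt)
})

test_that("speed converts to the expected per-frame displacement", {
  # 5 mm/s at 1000 Hz and 12.3 um pixels = 0.407 fine px; 25 mm/s = 2.033
  cfg <- benchConfig()
  dispPx <- function(speed) speed * 1000 / cfg@frameRate / cfg@finePixelUm
  expect_equal(dispPx(5), 0.4065, tolerance = 1e-4)
  expect_equal(dispPx(25), 2.0325, tolerance = 1e-4)

  st <- data.frame(id = 1L, row = 40, col = 40, dirRow = 1, dirCol = 0,
                   speed = 5, brightness = 1, lifetime = 20L, age = 0L,
                   tmplIdx = 1L)
  # perturbSd = 0 gives straight-line motion at exactly that step
  out <- st
  for (k in 1:4) out <- stepMotion(out, cfg, perturbSd = 0)
  expect_equal(out$row, 40 + 4 * dispPx(5), tolerance = 1e-10)
  expect_equal(out$col, 40)
})

test_that("bubbles expire after their lifetime and are respawned", {
  cfg <- benchConfig()
  set.seed(11)
  st <- data.frame(id = 1L, row = 40, col = 40, dirRow = 0, dirCol = 1,
                   speed = 5, brightness = 1, lifetime = 1L, age = 0L,
                   tmplIdx = 1L)
  out <- stepMotion(st, cfg)
  expect_false(1L %in% out$id)      # replaced by a fresh id
  expect_equal(nrow(out), 1L)       # density maintained
  expect_equal(out$age, 0L)
})

test_that("rendering maps fine positions onto the input grid", {
  cfg <- benchConfig()
  st <- data.frame(id = 1L, row = 40, col = 40, dirRow = 1, dirCol = 0,
                   speed = 5, brightness = 1, lifetime = 20L, age = 0L,
                   tmplIdx = 1L)
  # delta template (bank = NULL): fine (40, 40) lands in input pixel (20, 20)
  rf <- renderFrame(st, NULL, cfg)
  am <- which(rf$frame == max(rf$frame), arr.ind = TRUE)
  expect_equal(as.integer(am), c(21L, 21L))  # 1-based (21,21) = 0-based (20,20)
  # integrated intensity is conserved through block averaging
  expect_equal(sum(rf$frame) * cfg@downsample^2, 1)

  # additivity: two half-brightness bubbles at one spot equal one full one
  st2 <- rbind(st, st)
  st2$id <- 1:2; st2$brightness <- 0.5
  bank <- smallBank(1)
  rA <- renderFrame(st2, bank, cfg)
  stB <- st; stB$brightness <- 1
  rB <- renderFrame(stB, bank, cfg)
  expect_equal(rA$frame, rB$frame, tolerance = 1e-12)
})

test_that("sub-pixel rendering preserves the centre of mass", {
  cfg <- benchConfig()
  bank <- smallBank(1)
  st <- data.frame(id = 1L, row = 40.7, col = 39.2, dirRow = 1, dirCol = 0,
                   speed = 5, brightness = 1, lifetime = 20L, age = 0L,
                   tmplIdx = 1L)
  rf <- renderFrame(st, bank, cfg)
  fr <- rf$frame
  com <- c(sum((row(fr) - 1) * fr), sum((col(fr) - 1) * fr)) / sum(fr)
  # fine (40.7, 39.2) -> input ((40.7 - 0.5)/2, (39.2 - 0.5)/2)
  expect_lt(max(abs(com - c(20.1, 19.35))), 0.1)
})

test_that("density stays stationary and states within printed bounds", {
  cfg <- benchConfig()
  bank <- smallBank(5)
  conc <- 0.08
  target <- conc * fovAreaLambda2(cfg)
  means <- vapply(1:12, function(s) {
    sim <- simulateSequence(cfg, bank, NULL, 20, conc, seed = 300 + s)
    gt <- sim$gt
    expect_true(all(gt$row >= 0 & gt$row <= cfg@fovFine[1]))
    expect_true(all(gt$col >= 0 & gt$col <= cfg@fovFine[2]))
    counts <- table(factor(gt$frame, levels = 0:19))
    # respawn keeps the per-frame count exactly stationary within a sequence
    expect_equal(length(unique(as.integer(counts))), 1L)
    mean(counts)
  }, numeric(1))
  # across independent sequences the mean count is Poisson around the target
  se <- sqrt(target / 12)
  expect_lt(abs(mean(means) - target), 3 * se)
})

test_that("simulated speeds and lifetimes honour the sampling bounds", {
  cfg <- benchConfig()
  set.seed(31)
  pop <- initPopulation(cfg, 0.3)
  expect_true(all(pop$speed >= 5 & pop$speed <= 25))
  expect_true(all(pop$lifetime >= 1 & pop$lifetime <= 20))
  expect_true(all(abs(sqrt(pop$dirRow^2 + pop$dirCol^2) - 1) < 1e-9))
  expect_true(all(pop$brightness > 0))
})
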
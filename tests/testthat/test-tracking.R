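test_that("frame linking picks the assignment with minimum total cost", {
  # crossing configuration: pairing (1->1, 2->2) costs 2, crossing costs 10
  a <- data.frame(row = c(0, 10), col = c(0, 0))
  b <- data.frame(row = c(1, 11), col = c(0, 0))
  m <- linkFrames(a, b, maxDist = 6)
  expect_equal(m, c(1L, 2L))
  # gating: a 10 px jump with maxDist 5 stays unlinked
  expect_true(is.na(linkFrames(data.frame(row = 0, col = 0),
                               data.frame(row = 10, col = 0), 5)))
  # empty target frame terminates everything
  expect_equal(linkFrames(a, a[0, ], 5), rep(NA_integer_, 2))
})

test_that("segment joining honours the gap, distance and angle gates", {
  # collinear segments separated by one missing frame are joined
  segA <- data.frame(frame = 0:4, row = 0:4, col = rep(0, 5))
  segB <- data.frame(frame = 6:10, row = 6:10, col = rep(0, 5))
  tr <- linkSegments(list(segA, segB), maxDist = 3, maxGap = 2L)
  expect_length(tr, 1L)
  expect_equal(tr[[1]]$frame, c(0:4, 6:10))

  # a join requiring a right-angle turn is rejected
  segC <- data.frame(frame = 6:10, row = rep(4, 5), col = 2 + 0:4 * 0.01)
  trC <- linkSegments(list(segA, segC), maxDist = 3, maxGap = 2L,
                      maxAngle = 45)
  expect_length(trC, 2L)

  # with three mutually joinable segments, each end joins at most once
  segD <- data.frame(frame = 6:8, row = 6:8, col = rep(0.5, 3))
  trD <- linkSegments(list(segA, segB, segD), maxDist = 3, maxGap = 2L)
  expect_length(trD, 2L)
  expect_equal(sum(vapply(trD, nrow, integer(1))), 13L)
})

test_that("persistence filtering uses the 10-frame span rule", {
  mk <- function(n) data.frame(frame = seq_len(n) - 1, row = seq_len(n),
                               col = 0)
  expect_length(filterTracks(list(mk(9)), 10L), 0L)
  expect_length(filterTracks(list(mk(10)), 10L), 1L)
  tracks <- list(mk(5), mk(12), mk(10), mk(9))
  expect_lte(length(filterTracks(tracks, 10L)), length(tracks))
  expect_length(filterTracks(tracks, 10L), 2L)
})

test_that("straight-line ground truth is recovered with correct identity", {
  cfg <- benchConfig()
  conc <- 0.05
  set.seed(41)
  # build straight-line GT directly (perturbSd = 0 flow): long-lived bubbles
  nMB <- 12
  gt <- do.call(rbind, lapply(seq_len(nMB), function(id) {
    r0 <- runif(1, 15, 65); c0 <- runif(1, 15, 65)
    th <- runif(1, 0, 2 * pi)
    sp <- runif(1, 5, 25) * 1000 / cfg@frameRate / cfg@finePixelUm
    len <- sample(12:40, 1)
    t0 <- sample(0:(50 - len), 1)
    data.frame(frame = t0 + seq_len(len) - 1, id = id,
               row = r0 + (seq_len(len) - 1) * sp * cos(th),
               col = c0 + (seq_len(len) - 1) * sp * sin(th))
  }))
  gt <- gt[gt$row > 0 & gt$row < 79 & gt$col > 0 & gt$col < 79, ]
  locs <- data.frame(frame = gt$frame, row = gt$row, col = gt$col)
  tracks <- trackLocalizations(locs, cfg, minPersistence = 10L)

  # no detection is used twice; frames strictly increase within tracks
  key <- paste(tracks$frame, round(tracks$row, 6), round(tracks$col, 6))
  expect_false(any(duplicated(key)))
  for (id in unique(tracks$track)) {
    fr <- tracks$frame[tracks$track == id]
    expect_true(all(diff(fr) > 0))
  }

  # every GT bubble with >= 10 frames is recovered by a track whose points
  # match its positions within 1 fine px
  spans <- table(gt$id)
  longIds <- as.integer(names(spans)[spans >= 10])
  recovered <- vapply(longIds, function(id) {
    g <- gt[gt$id == id, ]
    hits <- vapply(unique(tracks$track), function(tid) {
      tr <- tracks[tracks$track == tid, ]
      mg <- merge(g, tr, by = "frame")
      if (nrow(mg) < 10) return(FALSE)
      all(sqrt((mg$row.x - mg$row.y)^2 + (mg$col.x - mg$col.y)^2) < 1)
    }, logical(1))
    any(hits)
  }, logical(1))
  expect_gte(mean(recovered), 0.95)
  expect_equal(conc, 0.05)
})

test_that("track summaries recover speed and axial direction", {
  cfg <- benchConfig()
  # bubble moving up (toward the transducer) at 10 mm/s
  sp <- 10 * 1000 / cfg@frameRate / cfg@finePixelUm
  tr <- data.frame(track = 1L, frame = 0:14, row = 50 - (0:14) * sp,
                   col = rep(10, 15))
  s <- trackSummary(tr, cfg)
  expect_equal(s$meanSpeed, 10, tolerance = 1e-9)
  expect_equal(s$directionSign, 1)
  trDown <- tr; trDown$row <- 50 + (0:14) * sp
  expect_equal(trackSummary(trDown, cfg)$directionSign, -1)
})
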
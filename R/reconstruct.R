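# Super-resolved outputs from tracks: accumulation density maps, directional
# flow maps, per-pixel bubble-count time series, and functional activation
# maps correlated with a stimulation pattern.

#' Super-resolution accumulation grid helper
#'
#' Converts fine-grid pixel coordinates to accumulation-grid indices:
#' positions (in micrometres) are first rounded to the `roundUm` grid
#' (lambda/10 by convention) and then binned into `gridUm` pixels
#' (lambda/5 reconstruction grid).
#'
#' @param rowPx,colPx fine-grid coordinates (0-based).
#' @param cfg an [ImagingConfig-class].
#' @param gridUm reconstruction pixel size (default lambda/5).
#' @param roundUm rounding grid (default lambda/10).
#' @return list `row`, `col` of 0-based integer bin indices and `dim` of the
#'   reconstruction grid.
#' @export
toReconGrid <- function(rowPx, colPx, cfg, gridUm = NULL, roundUm = NULL) {
  lam <- cfg@wavelengthUm
  if (is.null(gridUm)) gridUm <- lam / 5
  if (is.null(roundUm)) roundUm <- lam / 10
  stopIfNot(gridUm > 0, "grid must be positive")
  rUm <- round(rowPx * cfg@finePixelUm / roundUm) * roundUm
  cUm <- round(colPx * cfg@finePixelUm / roundUm) * roundUm
  dimOut <- ceiling(cfg@fovFine * cfg@finePixelUm / gridUm)
  r <- pmin(pmax(floor(rUm / gridUm), 0), dimOut[1] - 1)
  c <- pmin(pmax(floor(cUm / gridUm), 0), dimOut[2] - 1)
  list(row = as.integer(r), col = as.integer(c), dim = as.integer(dimOut))
}

#' Accumulate track points into a super-resolved density map
#'
#' Every track point increments its reconstruction-grid pixel by one; total
#' mass equals the number of accumulated points.
#'
#' @param tracks track data.frame (`track`, `frame`, `row`, `col`).
#' @param cfg an [ImagingConfig-class].
#' @param gridUm reconstruction pixel size (default lambda/5).
#' @param roundUm localization rounding grid (default lambda/10).
#' @return matrix of per-pixel counts.
#' @export
accumulateDensity <- function(tracks, cfg, gridUm = NULL, roundUm = NULL) {
  g <- toReconGrid(tracks$row, tracks$col, cfg, gridUm, roundUm)
  dens <- matrix(0, g$dim[1], g$dim[2])
  if (length(g$row))
    for (i in seq_along(g$row))
      dens[g$row[i] + 1, g$col[i] + 1] <- dens[g$row[i] + 1, g$col[i] + 1] + 1
  dens
}

#' Directional flow map
#'
#' Like [accumulateDensity()] but each point contributes its axial direction
#' sign: +1 when the local track velocity points toward the transducer
#' (decreasing row), -1 away, 0 for purely lateral steps. The magnitude of a
#' pixel is the net signed count.
#'
#' @inheritParams accumulateDensity
#' @return signed matrix.
#' @export
directionalMap <- function(tracks, cfg, gridUm = NULL, roundUm = NULL) {
  g <- toReconGrid(tracks$row, tracks$col, cfg, gridUm, roundUm)
  dmap <- matrix(0, g$dim[1], g$dim[2])
  for (id in unique(tracks$track)) {
    sel <- which(tracks$track == id)
    tr <- tracks[sel, , drop = FALSE]
    n <- nrow(tr)
    if (n < 2) next
    # local axial velocity by central differences
    vr <- numeric(n)
    vr[1] <- tr$row[2] - tr$row[1]
    vr[n] <- tr$row[n] - tr$row[n - 1]
    if (n > 2) vr[2:(n - 1)] <- (tr$row[3:n] - tr$row[1:(n - 2)]) / 2
    sgn <- -sign(vr)
    for (j in seq_len(n)) {
      r <- g$row[sel[j]] + 1; c <- g$col[sel[j]] + 1
      dmap[r, c] <- dmap[r, c] + sgn[j]
    }
  }
  dmap
}

#' Per-pixel microbubble count time series
#'
#' Counts, for every reconstruction pixel and every time window of
#' `windowS` seconds, the number of *distinct* tracks passing through the
#' pixel during the window (a track lingering in a pixel still counts once
#' per window).
#'
#' @inheritParams accumulateDensity
#' @param windowS window length in seconds (default 1).
#' @param nFrames total frames in the acquisition (defaults to the largest
#'   track frame + 1).
#' @return 3-D array (rows, cols, windows) of counts.
#' @export
mbCountSeries <- function(tracks, cfg, gridUm = NULL, roundUm = NULL,
                          windowS = 1, nFrames = NULL) {
  g <- toReconGrid(tracks$row, tracks$col, cfg, gridUm, roundUm)
  framesPerWin <- cfg@frameRate * windowS
  if (is.null(nFrames))
    nFrames <- if (nrow(tracks)) max(tracks$frame) + 1 else 0
  nWin <- max(ceiling(nFrames / framesPerWin), 1)
  arr <- array(0, c(g$dim[1], g$dim[2], nWin))
  if (nrow(tracks) == 0) return(arr)
  win <- pmin(floor(tracks$frame / framesPerWin), nWin - 1)
  key <- paste(tracks$track, g$row, g$col, win)
  first <- !duplicated(key)
  idx <- cbind(g$row[first] + 1, g$col[first] + 1, win[first] + 1)
  for (i in seq_len(nrow(idx)))
    arr[idx[i, 1], idx[i, 2], idx[i, 3]] <- arr[idx[i, 1], idx[i, 2], idx[i, 3]] + 1
  arr
}

#' Stimulation pattern for functional analysis
#'
#' Per-second binary stimulation state over repeated cycles: `stimS` seconds
#' of stimulation, `transitionS` seconds of transition (excluded from
#' analysis), `restS` seconds of stable rest. The analysis mask covers the
#' stimulation and stable-rest periods only.
#'
#' @param nCycles number of cycles (the reference protocol uses 15).
#' @param stimS,transitionS,restS cycle phase lengths in seconds
#'   (defaults 30/10/30).
#' @return list `A` (0/1 per second), `mask` (logical per second),
#'   `secondsPerCycle`.
#' @export
stimulationPattern <- function(nCycles = 15, stimS = 30, transitionS = 10,
                               restS = 30) {
  cyc <- c(rep(1, stimS), rep(0, transitionS), rep(0, restS))
  msk <- c(rep(TRUE, stimS), rep(FALSE, transitionS), rep(TRUE, restS))
  list(A = rep(cyc, nCycles), mask = rep(msk, nCycles),
       secondsPerCycle = stimS + transitionS + restS)
}

#' Functional activation map
#'
#' Pearson correlation, over the analysis mask (stimulation + stable rest
#' seconds), between each pixel's bubble-count series and the stimulation
#' pattern. Zero-variance pixel series get r = 0 and are flagged. A pixel is
#' *activated* when r exceeds 0.2 (strict).
#'
#' @param series 3-D count array from [mbCountSeries()] (windows must align
#'   with the pattern's seconds) or a pixels x time matrix.
#' @param pattern a [stimulationPattern()] list.
#' @param threshold activation threshold on r (default 0.2).
#' @return list `r` (correlation map), `activated` (logical map), `flat`
#'   (logical map of zero-variance pixels).
#' @export
activationMap <- function(series, pattern, threshold = 0.2) {
  if (length(dim(series)) == 3) {
    d <- dim(series)
    mat <- matrix(series, d[1] * d[2], d[3])
    shape <- d[1:2]
  } else {
    mat <- as.matrix(series)
    shape <- c(nrow(mat), 1L)
  }
  stopIfNot(ncol(mat) == length(pattern$A),
            "series length must match the stimulation pattern")
  A <- pattern$A[pattern$mask]
  stopIfNot(sd(A) > 0, "pattern is constant on the analysis mask")
  S <- mat[, pattern$mask, drop = FALSE]
  sdS <- apply(S, 1, sd)
  flat <- sdS == 0
  r <- numeric(nrow(S))
  if (any(!flat))
    r[!flat] <- suppressWarnings(as.numeric(cor(t(S[!flat, , drop = FALSE]), A)))
  r[flat] <- 0
  rMap <- matrix(r, shape[1], shape[2])
  list(r = rMap, activated = rMap > threshold,
       flat = matrix(flat, shape[1], shape[2]))
}

#' Count activated pixels in a region of interest
#'
#' @param map result of [activationMap()] (or a bare correlation matrix).
#' @param roi logical matrix of the same shape (default: everything).
#' @param threshold activation threshold (strict >; default 0.2).
#' @return integer count.
#' @export
activatedPixelCount <- function(map, roi = NULL, threshold = 0.2) {
  r <- if (is.list(map)) map$r else map
  if (is.null(roi)) roi <- matrix(TRUE, nrow(r), ncol(r))
  stopIfNot(all(dim(roi) == dim(r)), "roi shape mismatch")
  sum(r[roi] > threshold)
}

#' Synthetic functional acquisition: modulated and null vessels
#'
#' Emulates the per-second bubble-count series of vessels under a cyclic
#' stimulation protocol: counts are Poisson with a baseline rate, multiplied
#' by `stimGain` during stimulation seconds for the modulated vessels. Used
#' to validate activation mapping end to end.
#'
#' @param pattern a [stimulationPattern()] list.
#' @param nModulated,nNull number of modulated / unmodulated vessel pixels.
#' @param baselineRate mean bubbles per second at rest.
#' @param stimGain multiplicative rate change during stimulation (the
#'   reference scenario doubles the rate).
#' @param seed optional integer seed.
#' @return list `series` (pixels x seconds matrix), `modulated` (logical).
#' @export
simulateFulmSeries <- function(pattern, nModulated = 5, nNull = 5,
                               baselineRate = 5, stimGain = 2, seed = NULL) {
  withSeed(seed, {
    nSec <- length(pattern$A)
    n <- nModulated + nNull
    rate <- matrix(baselineRate, n, nSec)
    if (nModulated > 0)
      rate[seq_len(nModulated), pattern$A == 1] <- baselineRate * stimGain
    series <- matrix(rpois(n * nSec, rate), n, nSec)
    list(series = series, modulated = rep(c(TRUE, FALSE), c(nModulated, nNull)))
  })
}
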
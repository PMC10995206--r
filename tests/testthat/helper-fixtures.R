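# Shared in-code fixtures: a small bench configuration (kept tiny so the
# default run stays fast) and convenience builders.

# the benchmark-style configuration: 20 MHz, 12.3 um fine pixels, 80x80 fine
# grid block-averaged x2 into 40x40 input frames
benchConfig <- function(fov = c(80L, 80L)) imagingConfig(fovFine = fov)

# small isotropic-Gaussian bank on the fine grid
smallBank <- function(n = 10, seed = 1, side = 13L, sigmaRange = c(2, 2)) {
  gaussianTemplateBank(n, sigmaRange = sigmaRange, side = side,
                       muImax = 1, sigmaImax = 0.25, seed = seed)
}

# constant-sigma noise model matched to a config's input grid
inputNoise <- function(cfg, sigma = 0.1) {
  noiseModel(sigma, cfg@fovFine / cfg@downsample)
}

# build a DecodeOutput with constant channels, overriding selected pixels
constOutput <- function(H, W, p = 0, dRow = 0, dCol = 0, I = 1,
                        sRow = 1, sCol = 1, sI = 1) {
  m <- function(v) matrix(v, H, W)
  new("DecodeOutput", p = m(p), dRow = m(dRow), dCol = m(dCol), I = m(I),
      sigmaRow = m(sRow), sigmaCol = m(sCol), sigmaI = m(sI),
      B = m(1e-9), sigmaB = m(1))
}

# brute-force optimal gated matching by permutation enumeration (oracle for
# matchLocalizations on tiny instances): maximise matches, then minimise
# total distance
bruteMatch <- function(pred, gt, radius) {
  nP <- nrow(pred); nG <- nrow(gt)
  if (nP == 0 || nG == 0)
    return(list(TP = 0L, cost = 0))
  d <- sqrt(outer(pred$row, gt$row, "-")^2 + outer(pred$col, gt$col, "-")^2)
  best <- list(TP = -1L, cost = Inf)
  gtIdx <- seq_len(nG)
  # enumerate subsets of predictions mapped injectively into gt
  rec <- function(i, used, tp, cost) {
    maxTp <- tp + (nP - i + 1L)
    if (maxTp < best$TP ||
        (maxTp == best$TP && cost >= best$cost - 1e-12)) return()
    if (i > nP) {
      if (tp > best$TP || (tp == best$TP && cost < best$cost - 1e-12))
        best <<- list(TP = tp, cost = cost)
      return()
    }
    rec(i + 1L, used, tp, cost)  # leave pred i unmatched
    for (j in gtIdx[!used]) {
      if (d[i, j] <= radius)
        rec(i + 1L, replace(used, j, TRUE), tp + 1L, cost + d[i, j])
    }
  }
  rec(1L, rep(FALSE, nG), 0L, 0)
  best
}
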
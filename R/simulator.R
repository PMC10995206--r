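# Ground-truth microbubble simulator: population initialization, stochastic
# motion with lifetime/respawn, sub-pixel rendering on the fine grid and
# block-average downsampling to the network input grid.

SPEED_RANGE_MM_S <- c(5, 25)
LIFETIME_RANGE <- c(1L, 20L)

# draw n fresh bubble states (used for init and respawn)
drawStates <- function(n, cfg, muImax, sigmaImax, nTemplates, idStart) {
  theta <- runif(n, 0, 2 * pi)
  data.frame(
    id = idStart + seq_len(n) - 1L,
    row = runif(n, 0, cfg@fovFine[1] - 1e-9),
    col = runif(n, 0, cfg@fovFine[2] - 1e-9),
    dirRow = cos(theta), dirCol = sin(theta),
    speed = runif(n, SPEED_RANGE_MM_S[1], SPEED_RANGE_MM_S[2]),
    brightness = pmax(rnorm(n, muImax, sigmaImax), 1e-6),
    lifetime = sample.int(LIFETIME_RANGE[2], n, replace = TRUE),
    age = rep(0L, n),
    tmplIdx = sample.int(max(nTemplates, 1L), n, replace = TRUE)
  )
}

#' Initialize a microbubble population
#'
#' Draws the per-frame bubble count from a Poisson distribution with mean
#' `concentration * FOV area (lambda^2)`, positions uniform in the fine-grid
#' FOV, speeds uniform in 5-25 mm/s, lifetimes uniform on 1..20 frames,
#' directions uniform on the unit circle, and brightness from
#' N(muImax, sigmaImax) truncated at zero. Each bubble is also assigned a
#' fixed template index so its point-spread signature is coherent over its
#' lifetime.
#'
#' @param cfg an [ImagingConfig-class]; the FOV must be at least 1 lambda^2.
#' @param concentration areal concentration in bubbles per squared
#'   wavelength (MBs/lambda^2).
#' @param bank a [TemplateBank-class] supplying brightness statistics and the
#'   number of templates (optional; defaults give unit brightness).
#' @param seed optional integer seed.
#' @return a data.frame of bubble states (one row per bubble).
#' @export
initPopulation <- function(cfg, concentration, bank = NULL, seed = NULL) {
  stopIfNot(concentration > 0, "concentration must be positive")
  stopIfNot(fovAreaLambda2(cfg) >= 1, "FOV smaller than 1 lambda^2")
  mu <- if (is.null(bank)) 1 else bank@muImax
  sig <- if (is.null(bank)) 0.25 else bank@sigmaImax
  nt <- if (is.null(bank)) 1L else length(bank@templates)
  withSeed(seed, {
    n <- rpois(1, concentration * fovAreaLambda2(cfg))
    drawStates(n, cfg, mu, sig, nt, 1L)
  })
}

#' Advance the bubble population by one frame
#'
#' Perturbs each direction vector with independent N(0, perturbSd^2)
#' components and renormalizes, displaces each bubble by
#' `speed * dt` (converted to fine pixels), increments ages, and replaces
#' expired or out-of-FOV bubbles with fresh draws (new ids) so the expected
#' density stays stationary.
#'
#' @param states bubble state data.frame from [initPopulation()].
#' @param cfg an [ImagingConfig-class].
#' @param bank template bank for respawn draws (same role as in
#'   [initPopulation()]).
#' @param perturbSd SD of the per-component direction perturbation
#'   (default 0.2).
#' @return updated state data.frame.
#' @export
stepMotion <- function(states, cfg, bank = NULL, perturbSd = 0.2) {
  n <- nrow(states)
  if (n > 0) {
    dr <- states$dirRow + rnorm(n, 0, perturbSd)
    dc <- states$dirCol + rnorm(n, 0, perturbSd)
    nrm <- sqrt(dr^2 + dc^2)
    bad <- nrm < 1e-12
    dr[bad] <- states$dirRow[bad]; dc[bad] <- states$dirCol[bad]
    nrm[bad] <- 1
    states$dirRow <- dr / nrm
    states$dirCol <- dc / nrm
    # displacement in fine px: speed mm/s -> um per frame -> px
    dispPx <- states$speed * 1000 / cfg@frameRate / cfg@finePixelUm
    states$row <- states$row + states$dirRow * dispPx
    states$col <- states$col + states$dirCol * dispPx
    states$age <- states$age + 1L
  }
  gone <- states$age >= states$lifetime |
    states$row < 0 | states$row > cfg@fovFine[1] - 1e-9 |
    states$col < 0 | states$col > cfg@fovFine[2] - 1e-9
  nGone <- sum(gone)
  if (nGone > 0) {
    mu <- if (is.null(bank)) 1 else bank@muImax
    sig <- if (is.null(bank)) 0.25 else bank@sigmaImax
    nt <- if (is.null(bank)) 1L else length(bank@templates)
    nextId <- if (n > 0) max(states$id) + 1L else 1L
    states[gone, ] <- drawStates(nGone, cfg, mu, sig, nt, nextId)
  }
  states
}

#' Render one frame from the current bubble states
#'
#' Each bubble stamps its (per-bubble fixed) template, scaled by its
#' brightness, at its continuous fine-grid position via bilinear sub-pixel
#' shifting; overlapping bubbles add. The fine frame is then block-averaged
#' by the configured downsampling factor to the network input grid. When
#' `bank` is NULL a single-pixel delta template is used.
#'
#' @param states bubble state data.frame.
#' @param bank a [TemplateBank-class] or NULL.
#' @param cfg an [ImagingConfig-class]; `fovFine` must be divisible by the
#'   downsampling factor.
#' @return list with `frame` (input-grid matrix), `fine` (fine-grid matrix)
#'   and `gt` (data.frame id, row, col, brightness on the fine grid).
#' @export
renderFrame <- function(states, bank, cfg) {
  stopIfNot(all(cfg@fovFine %% cfg@downsample == 0),
            "fovFine must be divisible by downsample")
  fine <- matrix(0, cfg@fovFine[1], cfg@fovFine[2])
  if (!is.null(bank)) {
    side <- nrow(bank@templates[[1]]@patch)
    stopIfNot(side <= min(cfg@fovFine), "template larger than FOV")
  }
  if (nrow(states) > 0) {
    for (i in seq_len(nrow(states))) {
      if (is.null(bank)) {
        tp <- matrix(1, 1, 1); pr <- 0; pc <- 0
      } else {
        tmpl <- bank@templates[[states$tmplIdx[i]]]
        tp <- tmpl@patch
        ctr <- (nrow(tp) - 1) / 2
        pr <- ctr + tmpl@peakOffset[1]
        pc <- ctr + tmpl@peakOffset[2]
      }
      cpp_stamp(fine, tp, states$row[i], states$col[i], pr, pc,
                states$brightness[i])
    }
  }
  gt <- data.frame(id = states$id, row = states$row, col = states$col,
                   brightness = states$brightness)
  list(frame = blockAverage(fine, cfg@downsample), fine = fine, gt = gt)
}

#' Block-average downsampling
#'
#' Averages non-overlapping `d x d` blocks. Integrated intensity (pixel sum
#' times pixel area) is conserved exactly for FOVs divisible by `d`.
#'
#' @param m matrix with dimensions divisible by `d`.
#' @param d integer factor.
#' @return downsampled matrix.
#' @export
blockAverage <- function(m, d) {
  if (d == 1) return(m)
  H <- nrow(m); W <- ncol(m)
  dim(m) <- c(d, H / d, d, W / d)
  t1 <- colSums(m)                      # (H/d, d, W/d)
  t2 <- colSums(aperm(t1, c(2, 1, 3)))  # (H/d, W/d)
  t2 / d^2
}

#' Simulate a labeled frame sequence
#'
#' Chains population initialization, per-frame rendering and motion stepping,
#' then corrupts each input-grid frame with Rician noise. Fully reproducible
#' from the seed.
#'
#' @param cfg an [ImagingConfig-class].
#' @param bank a [TemplateBank-class] (or NULL for delta templates).
#' @param noiseModel a [NoiseModel-class] on the input grid, or NULL for
#'   noise-free output.
#' @param nFrames number of frames (>= 1).
#' @param concentration bubble concentration in MBs/lambda^2.
#' @param seed integer seed.
#' @return list with `stack` (a [FrameStack-class], stage "input") and `gt`
#'   (data.frame frame, id, row, col, brightness; fine-grid coordinates,
#'   0-based frames).
#' @export
simulateSequence <- function(cfg, bank, noiseModel = NULL, nFrames,
                             concentration, seed = 1L) {
  stopIfNot(nFrames >= 1, "nFrames must be >= 1")
  withSeed(seed, {
    states <- initPopulation(cfg, concentration, bank)
    H <- cfg@fovFine[1] / cfg@downsample
    W <- cfg@fovFine[2] / cfg@downsample
    dat <- array(0, c(nFrames, H, W))
    gts <- vector("list", nFrames)
    for (t in seq_len(nFrames)) {
      rf <- renderFrame(states, bank, cfg)
      fr <- rf$frame
      if (!is.null(noiseModel)) fr <- addRicianNoise(fr, noiseModel)
      dat[t, , ] <- fr
      if (nrow(rf$gt) > 0)
        gts[[t]] <- cbind(frame = t - 1L, rf$gt)
      states <- stepMotion(states, cfg, bank)
    }
    gt <- do.call(rbind, gts[!vapply(gts, is.null, logical(1))])
    if (is.null(gt))
      gt <- data.frame(frame = integer(), id = integer(), row = numeric(),
                       col = numeric(), brightness = numeric())
    list(stack = frameStack(dat, cfg, "input"), gt = gt)
  })
}

#' Map fine-grid coordinates to input-grid coordinates
#'
#' Fine pixels `d*k .. d*k+d-1` average into input pixel `k`, whose centre
#' corresponds to fine coordinate `d*k + (d-1)/2`; the map is therefore
#' `(x_fine - (d-1)/2) / d`.
#'
#' @param x fine-grid coordinates (0-based pixel centres at integers).
#' @param d integer downsampling factor.
#' @return input-grid coordinates.
#' @export
fineToInput <- function(x, d) (x - (d - 1) / 2) / d

#' @rdname fineToInput
#' @export
inputToFine <- function(x, d) x * d + (d - 1) / 2
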
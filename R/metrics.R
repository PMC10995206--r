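# Benchmark machinery: gated optimal matching of predictions to ground
# truth, detection accuracy, miss rate, localization error, vessel filling,
# and the concentration sweep harness.

#' Match predicted localizations to ground truth
#'
#' Minimum-total-distance one-to-one assignment restricted to pairs within
#' `radius` (optimal, not greedy: greedy matching inflates accuracy at high
#' density). Unmatched predictions become false positives, unmatched ground
#' truth false negatives.
#'
#' @param pred,gt data.frames with `row`, `col` columns (same grid).
#' @param radius matching radius in pixels (> 0). The reference criterion is
#'   0.32 lambda; use [matchRadiusPx()] to express it in pixels.
#' @param mode "optimal" (default) or "greedy" (for sensitivity checks).
#' @return a `MatchResult` list: `tpPairs` (data.frame pred, gt, distance),
#'   `fp`, `fn` (index vectors), `radius`, and counts `TP`, `FP`, `FN`.
#' @export
matchLocalizations <- function(pred, gt, radius = 5, mode = c("optimal", "greedy")) {
  mode <- match.arg(mode)
  stopIfNot(radius > 0, "radius must be positive")
  nP <- nrow(pred); nG <- nrow(gt)
  tp <- data.frame(pred = integer(), gt = integer(), distance = numeric())
  if (nP > 0 && nG > 0) {
    cost <- sqrt(outer(pred$row, gt$row, "-")^2 +
                 outer(pred$col, gt$col, "-")^2)
    if (mode == "optimal") {
      m <- gatedAssign(cost, radius)
      sel <- which(!is.na(m))
      if (length(sel))
        tp <- data.frame(pred = sel, gt = m[sel],
                         distance = cost[cbind(sel, m[sel])])
    } else {
      usedG <- logical(nG)
      ord <- order(cost)
      for (k in ord) {
        if (cost[k] > radius) break
        i <- (k - 1) %% nP + 1
        j <- (k - 1) %/% nP + 1
        if (i %in% tp$pred || usedG[j]) next
        tp <- rbind(tp, data.frame(pred = i, gt = j, distance = cost[i, j]))
        usedG[j] <- TRUE
      }
    }
  }
  res <- list(tpPairs = tp,
              fp = setdiff(seq_len(nP), tp$pred),
              fn = setdiff(seq_len(nG), tp$gt),
              radius = radius,
              TP = nrow(tp), FP = nP - nrow(tp), FN = nG - nrow(tp))
  class(res) <- "MatchResult"
  res
}

#' Matching radius of 0.32 wavelengths in pixels
#'
#' @param cfg an [ImagingConfig-class].
#' @param pixelUm pixel pitch of the localization grid (default fine pixel).
#' @param lambdaFrac fraction of the wavelength (default 0.32).
#' @return radius in pixels.
#' @export
matchRadiusPx <- function(cfg, pixelUm = NULL, lambdaFrac = 0.32) {
  if (is.null(pixelUm)) pixelUm <- cfg@finePixelUm
  lambdaFrac * cfg@wavelengthUm / pixelUm
}

#' Detection accuracy: TP / (TP + FP)
#'
#' Fraction of correct localizations among all predicted localizations.
#' Undefined (flagged NaN) when there are no predictions.
#'
#' @param m a `MatchResult` from [matchLocalizations()].
#' @return scalar in `[0, 1]`, or NaN.
#' @export
detectionAccuracy <- function(m) {
  if (m$TP + m$FP == 0) return(NaN)
  m$TP / (m$TP + m$FP)
}

#' Miss rate: FN / (TP + FN)
#'
#' Fraction of ground-truth bubbles that were not localized. Undefined
#' (flagged NaN) for empty ground truth.
#'
#' @param m a `MatchResult`.
#' @return scalar in `[0, 1]`, or NaN.
#' @export
missRate <- function(m) {
  if (m$TP + m$FN == 0) return(NaN)
  m$FN / (m$TP + m$FN)
}

#' Localization error over true positives
#'
#' Averaged root mean-squared distance between matched pairs,
#' `sqrt(mean(((dx^2 + dy^2) / 2)))` -- note the per-pair division by two
#' inside the root, following the benchmark definition.
#'
#' @param m a `MatchResult`.
#' @param pred,gt the data.frames used for matching (for coordinates).
#' @return error in pixels, or NaN for zero true positives.
#' @export
localizationError <- function(m, pred, gt) {
  if (m$TP == 0) return(NaN)
  dr <- pred$row[m$tpPairs$pred] - gt$row[m$tpPairs$gt]
  dc <- pred$col[m$tpPairs$pred] - gt$col[m$tpPairs$gt]
  sqrt(mean((dr^2 + dc^2) / 2))
}

#' Vessel filling percentage
#'
#' Percentage of ground-truth vessel pixels covered by the reconstructed
#' map: `100 * |GT intersect ULM| / |GT|`. Pixels outside the ground truth
#' do not contribute.
#'
#' @param ulmBinary logical/0-1 matrix of the reconstruction.
#' @param gtBinary logical/0-1 matrix of the reference segmentation with at
#'   least one positive pixel.
#' @return percentage in `[0, 100]`.
#' @export
vesselFilling <- function(ulmBinary, gtBinary) {
  stopIfNot(all(dim(ulmBinary) == dim(gtBinary)), "shape mismatch")
  nGT <- sum(gtBinary > 0)
  stopIfNot(nGT > 0, "empty ground-truth mask")
  100 * sum(ulmBinary > 0 & gtBinary > 0) / nGT
}

#' Localization benchmark over a concentration sweep
#'
#' For each concentration, simulates a labeled sequence, runs the supplied
#' localizer, and aggregates per-frame detection accuracy, miss rate and
#' localization error (mean and SD over frames). The reference protocol
#' sweeps 0.02 to 0.37 bubbles per squared wavelength in steps of 0.02 with
#' 500 frames per concentration.
#'
#' @param localizer function(stack) -> data.frame with `frame` (0-based),
#'   `row`, `col` in fine-grid coordinates.
#' @param cfg an [ImagingConfig-class].
#' @param bank a [TemplateBank-class].
#' @param noiseModel a [NoiseModel-class] or NULL.
#' @param concentrations vector of concentrations (MBs/lambda^2).
#' @param nFrames frames per concentration.
#' @param radius matching radius in fine px (default 0.32 lambda).
#' @param seed integer seed.
#' @return data.frame with one row per concentration:
#'   `concentration, accuracy_mean, accuracy_sd, miss_mean, miss_sd,
#'   error_mean, error_sd`.
#' @export
benchmarkSweep <- function(localizer, cfg, bank, noiseModel = NULL,
                           concentrations = seq(0.02, 0.37, by = 0.02),
                           nFrames = 100, radius = NULL, seed = 1L) {
  if (is.null(radius)) radius <- matchRadiusPx(cfg)
  rows <- lapply(seq_along(concentrations), function(ci) {
    conc <- concentrations[ci]
    sim <- simulateSequence(cfg, bank, noiseModel, nFrames, conc,
                            seed = deriveSeed(seed, paste0("bench", ci)))
    pred <- localizer(sim$stack)
    acc <- miss <- err <- rep(NA_real_, nFrames)
    for (t in seq_len(nFrames) - 1L) {
      p <- pred[pred$frame == t, , drop = FALSE]
      g <- sim$gt[sim$gt$frame == t, , drop = FALSE]
      if (nrow(g) == 0) next
      m <- matchLocalizations(p, g, radius)
      acc[t + 1] <- detectionAccuracy(m)
      miss[t + 1] <- missRate(m)
      err[t + 1] <- localizationError(m, p, g)
    }
    data.frame(concentration = conc,
               accuracy_mean = mean(acc, na.rm = TRUE),
               accuracy_sd = sd(acc, na.rm = TRUE),
               miss_mean = mean(miss, na.rm = TRUE),
               miss_sd = sd(miss, na.rm = TRUE),
               error_mean = mean(err, na.rm = TRUE),
               error_sd = sd(err, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
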
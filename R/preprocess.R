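# Acquisition preprocessing: SVD clutter filtering on the Casorati matrix,
# per-acquisition 0-1 normalization, low-intensity thresholding, and grid
# upsampling for network input.

#' SVD clutter filter
#'
#' Decomposes the Casorati matrix (pixels x time) by SVD, zeroes the
#' `lowCut` lowest-order singular components (slowly varying tissue signal)
#' and optionally every component from `highCut` (0-based) upward, and
#' returns the magnitude of the reconstruction.
#'
#' @param stack a [FrameStack-class] with at least 2 frames.
#' @param lowCut number of lowest-order components removed (0 = identity on
#'   magnitudes); must be smaller than the matrix rank.
#' @param highCut optional 0-based index from which higher-order components
#'   are removed (noise cut).
#' @return filtered [FrameStack-class].
#' @export
svdFilter <- function(stack, lowCut = 1L, highCut = NULL) {
  dat <- stack@data
  T <- dim(dat)[1]
  stopIfNot(T >= 2, "need at least 2 frames")
  H <- dim(dat)[2]; W <- dim(dat)[3]
  caso <- matrix(aperm(dat, c(2, 3, 1)), H * W, T)
  rk <- min(dim(caso))
  stopIfNot(lowCut < rk, "lowCut must be smaller than the matrix rank")
  if (lowCut == 0 && is.null(highCut)) {
    out <- abs(dat)
  } else {
    sv <- svd(caso)
    d <- sv$d
    keep <- rep(TRUE, length(d))
    if (lowCut > 0) keep[seq_len(lowCut)] <- FALSE
    if (!is.null(highCut)) keep[highCut < seq_along(d)] <- FALSE
    rec <- sv$u[, keep, drop = FALSE] %*%
      (d[keep] * t(sv$v[, keep, drop = FALSE]))
    out <- aperm(array(abs(rec), c(H, W, T)), c(3, 1, 2))
  }
  frameStack(out, stack@config, "preprocessed")
}

#' Per-acquisition 0-1 normalization
#'
#' Rescales the whole acquisition block to `[0, 1]` using its global minimum
#' and maximum. Different acquisitions get independent scalings.
#'
#' @param stack a [FrameStack-class]; must not be constant.
#' @return normalized [FrameStack-class].
#' @export
normalizeAcquisition <- function(stack) {
  lo <- min(stack@data); hi <- max(stack@data)
  stopIfNot(hi > lo, "constant stack has a degenerate intensity range")
  frameStack((stack@data - lo) / (hi - lo), stack@config, "preprocessed")
}

#' Low-intensity background thresholding
#'
#' Sets values strictly below `threshold` to zero (the boundary value is
#' kept); values at or above are unchanged. The empirically useful range on
#' 0-1 normalized data is 0.1-0.2.
#'
#' @param stack a [FrameStack-class] on the 0-1 scale.
#' @param threshold scalar threshold (default 0.15).
#' @return thresholded [FrameStack-class].
#' @export
thresholdBackground <- function(stack, threshold = 0.15) {
  dat <- stack@data
  dat[dat < threshold] <- 0
  frameStack(dat, stack@config, "preprocessed")
}

#' Upsample a stack for network input
#'
#' Cubic-spline interpolation of each frame, by `axFactor` along rows
#' (axial) and `latFactor` along columns (lateral); output pixel sizes are
#' divided accordingly. `bilinear` is available for exactness checks.
#'
#' @param stack a [FrameStack-class].
#' @param axFactor axial upsampling factor (>= 1; default 2.5).
#' @param latFactor lateral upsampling factor (>= 1; default 5).
#' @param method "spline" (cubic; default) or "bilinear".
#' @return upsampled [FrameStack-class]; an input coordinate `x` maps to
#'   output coordinate `x * factor`.
#' @export
upsampleStack <- function(stack, axFactor = 2.5, latFactor = 5,
                          method = c("spline", "bilinear")) {
  method <- match.arg(method)
  stopIfNot(axFactor >= 1 && latFactor >= 1, "factors must be >= 1")
  dat <- stack@data
  T <- dim(dat)[1]; H <- dim(dat)[2]; W <- dim(dat)[3]
  Ho <- floor((H - 1) * axFactor) + 1
  Wo <- floor((W - 1) * latFactor) + 1
  rq <- (seq_len(Ho) - 1) / axFactor
  cq <- (seq_len(Wo) - 1) / latFactor
  interp1 <- function(y, xq) {
    if (method == "spline")
      spline(x = seq_along(y) - 1, y = y, xout = xq, method = "fmm")$y
    else
      approx(x = seq_along(y) - 1, y = y, xout = xq)$y
  }
  out <- array(0, c(T, Ho, Wo))
  for (t in seq_len(T)) {
    fr <- dat[t, , ]
    tmp <- apply(fr, 2, interp1, xq = rq)         # Ho x W
    out[t, , ] <- t(apply(tmp, 1, interp1, xq = cq))  # Ho x Wo
  }
  out[out < 0] <- 0  # spline overshoot on non-negative data
  frameStack(out, stack@config, "preprocessed")
}
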
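# Rician background noise: scale estimation from noise-only recordings,
# corruption of noise-free frames, and the density itself.

#' Estimate the per-pixel Rician noise scale
#'
#' From a noise-only recording (no imaging target), the per-pixel magnitude
#' is Rayleigh distributed with mean `sigma * sqrt(pi/2)`; the noise SD is
#' therefore estimated from the temporal mean as
#' `sigma_hat = sqrt(2/pi) * mean_t E(x, z, t)`, elementwise.
#'
#' @param noiseStack a [FrameStack-class] of noise-only frames (T >= 2,
#'   non-negative).
#' @return a [NoiseModel-class].
#' @examples
#' cfg <- imagingConfig(fovFine = c(8L, 8L))
#' ns <- frameStack(array(1, c(4, 4, 4)), cfg, stage = "noise")
#' sigmaMap(estimateSigma(ns))[1, 1]  # sqrt(2/pi) ~ 0.7979
#' @export
estimateSigma <- function(noiseStack) {
  dat <- noiseStack@data
  stopIfNot(dim(dat)[1] >= 2, "need at least 2 noise frames")
  stopIfNot(all(dat >= 0), "noise stack must be non-negative")
  sig <- sqrt(2 / pi) * apply(dat, c(2, 3), mean)
  new("NoiseModel", sigmaMap = sig, nSamples = dim(dat)[1])
}

#' Corrupt a noise-free frame with Rician noise
#'
#' Adds independent N(0, sigma^2) noise to the real and imaginary parts of
#' the (implicitly real, non-negative) frame and returns the magnitude:
#' `out = |nu + n_r + i n_i|`. The marginal of the output is exactly the
#' Rician density of [ricianPDF()].
#'
#' @param frame non-negative matrix of noise-free magnitudes.
#' @param model a [NoiseModel-class] whose sigma map matches the frame shape.
#' @param seed optional integer seed.
#' @return matrix of noisy magnitudes (always non-negative).
#' @export
addRicianNoise <- function(frame, model, seed = NULL) {
  sig <- model@sigmaMap
  stopIfNot(all(dim(frame) == dim(sig)), "frame/sigma map shape mismatch")
  withSeed(seed, {
    nr <- matrix(rnorm(length(frame), 0, sig), nrow(frame))
    ni <- matrix(rnorm(length(frame), 0, sig), nrow(frame))
    sqrt((frame + nr)^2 + ni^2)
  })
}

#' Rician probability density
#'
#' Density of the magnitude of a complex signal with noise-free magnitude
#' `nu` and independent additive Gaussian noise of SD `sigma` on both
#' components:
#' `p(I) = I/sigma^2 * exp(-(I^2 + nu^2) / (2 sigma^2)) * besselI0(I nu / sigma^2)`.
#' Evaluated with the exponentially scaled Bessel function for numerical
#' stability at large arguments. At `nu = 0` this reduces to the Rayleigh
#' density.
#'
#' @param I non-negative magnitudes at which to evaluate.
#' @param nu non-negative noise-free magnitude.
#' @param sigma noise SD, > 0.
#' @return density values.
#' @examples
#' ricianPDF(1, 0, 1)  # Rayleigh: exp(-0.5) ~ 0.6065
#' @export
ricianPDF <- function(I, nu, sigma) {
  stopIfNot(all(sigma > 0), "sigma must be positive")
  z <- I * nu / sigma^2
  # besselI(z, 0, expon.scaled) = I0(z) * exp(-z)
  I / sigma^2 * exp(-(I - nu)^2 / (2 * sigma^2)) * besselI(z, 0, expon.scaled = TRUE)
}
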
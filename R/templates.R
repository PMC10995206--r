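# Template bank construction: parametric Gaussian templates and patch
# extraction around detected peaks. The adversarial generator lives in
# lsgan.R.

#' Build a bivariate Gaussian microbubble template
#'
#' Discretizes a separable bivariate Gaussian on an odd-sided patch so that
#' the continuous peak (value 1) sits at the patch centre plus `peakOffset`.
#'
#' @param sigmaAxial axial (row) SD in patch pixels, > 0.
#' @param sigmaLateral lateral (col) SD in patch pixels, > 0.
#' @param side odd patch side length, at least 5 * max(sigma).
#' @param peakOffset numeric (row, col) sub-pixel offset of the peak from the
#'   patch centre.
#' @return an [MBTemplate-class].
#' @examples
#' t <- makeGaussianTemplate(2, 2, side = 21)
#' which(templatePatch(t) == 1, arr.ind = TRUE)  # centre pixel (11, 11)
#' @export
makeGaussianTemplate <- function(sigmaAxial, sigmaLateral, side = 65L,
                                 peakOffset = c(0, 0)) {
  stopIfNot(sigmaAxial > 0 && sigmaLateral > 0, "sigmas must be positive")
  stopIfNot(side %% 2 == 1, "side must be odd")
  stopIfNot(side >= 5 * max(sigmaAxial, sigmaLateral),
            "side must be at least 5 * max(sigma)")
  ctr <- (side - 1) / 2
  r <- (0:(side - 1)) - (ctr + peakOffset[1])
  c <- (0:(side - 1)) - (ctr + peakOffset[2])
  patch <- exp(-0.5 * outer(r^2 / sigmaAxial^2, c^2 / sigmaLateral^2, "+"))
  new("MBTemplate", patch = patch, peakOffset = as.numeric(peakOffset))
}

#' Extract microbubble templates around detected peaks
#'
#' Crops a square patch around each supplied peak so the peak sits at the
#' patch centre (the detected peak is taken as the true bubble position, so
#' the stored sub-pixel offset is zero). Brightness statistics `muImax` /
#' `sigmaImax` are the mean and population SD of the patch maxima *before*
#' per-patch peak normalization.
#'
#' @param stack a [FrameStack-class].
#' @param peaks list (one element per frame) of integer (row, col) matrices
#'   of peak positions, 0-based.
#' @param side odd patch side length (default 65).
#' @return a [TemplateBank-class] with `source = "extracted"`.
#' @export
extractTemplates <- function(stack, peaks, side = 65L) {
  stopIfNot(side %% 2 == 1, "side must be odd")
  dat <- stack@data
  stopIfNot(length(peaks) == dim(dat)[1],
            "peaks must have one entry per frame")
  half <- (side - 1) / 2
  H <- dim(dat)[2]; W <- dim(dat)[3]
  maxima <- numeric(0)
  patches <- list()
  nskip <- 0L
  for (t in seq_along(peaks)) {
    pk <- peaks[[t]]
    if (is.null(pk) || length(pk) == 0) next
    pk <- matrix(as.numeric(pk), ncol = 2)
    for (i in seq_len(nrow(pk))) {
      r <- round(pk[i, 1]); c <- round(pk[i, 2])
      if (r - half < 0 || r + half > H - 1 || c - half < 0 || c + half > W - 1) {
        nskip <- nskip + 1L
        next
      }
      patch <- dat[t, (r - half):(r + half) + 1, (c - half):(c + half) + 1]
      maxima <- c(maxima, max(patch))
      if (max(patch) > 0) patch <- patch / max(patch)
      patches[[length(patches) + 1L]] <-
        new("MBTemplate", patch = patch, peakOffset = c(0, 0))
    }
  }
  if (nskip > 0)
    warning(sprintf("%d peak(s) too close to the border were skipped", nskip))
  if (length(patches) == 0)
    stop("no patches survived extraction (empty bank)")
  mu <- mean(maxima)
  sig <- sqrt(mean((maxima - mu)^2))  # population SD
  new("TemplateBank", templates = patches, muImax = mu, sigmaImax = sig,
      source = "extracted")
}

#' Build a bank of random Gaussian templates
#'
#' Convenience generator of the parametric simulation condition: `n`
#' bivariate Gaussian templates with per-template SDs drawn uniformly from
#' `sigmaRange` (fine-grid pixels) and zero peak offset.
#'
#' @param n number of templates.
#' @param sigmaRange range of per-axis SDs (fine px); each template draws its
#'   axial and lateral SD independently.
#' @param side odd template side length (fine px).
#' @param muImax,sigmaImax brightness statistics assigned to the bank
#'   (intensity units); simulated bubbles draw brightness from
#'   N(muImax, sigmaImax).
#' @param seed optional integer seed.
#' @return a [TemplateBank-class] with `source = "gaussian"`.
#' @export
gaussianTemplateBank <- function(n = 50, sigmaRange = c(1.6, 2.4), side = 25L,
                                 muImax = 1, sigmaImax = 0.25, seed = NULL) {
  withSeed(seed, {
    tmpl <- lapply(seq_len(n), function(i) {
      makeGaussianTemplate(runif(1, sigmaRange[1], sigmaRange[2]),
                           runif(1, sigmaRange[1], sigmaRange[2]),
                           side = side)
    })
    new("TemplateBank", templates = tmpl, muImax = muImax,
        sigmaImax = sigmaImax, source = "gaussian")
  })
}

#' Fit an axis-aligned Gaussian to a template patch
#'
#' Least-squares fit of `a * exp(-((r-cr)^2 / (2 sr^2) + (c-cc)^2 /
#' (2 sc^2))) + b` to the patch, initialized from intensity-weighted
#' moments. This estimates the template width robustly in the presence of a
#' low-intensity background haze, which inflates raw second moments.
#'
#' @param patch non-negative matrix (or an [MBTemplate-class]).
#' @return named vector `sigmaRow`, `sigmaCol`, `centerRow`, `centerCol`,
#'   `amplitude`, `offset`, `rss`.
#' @export
fitTemplateSigma <- function(patch) {
  if (is(patch, "MBTemplate")) patch <- patch@patch
  rows <- row(patch) - 1; cols <- col(patch) - 1
  mom <- patchMoments(patch)
  par0 <- c(mom$com, log(pmax(pmin(mom$sd, nrow(patch) / 2), 0.3)))
  obj <- function(par) {
    g <- exp(-((rows - par[1])^2 / (2 * exp(2 * par[3])) +
               (cols - par[2])^2 / (2 * exp(2 * par[4]))))
    # closed-form amplitude and offset given the shape
    X <- cbind(g = as.vector(g), 1)
    cf <- tryCatch(qr.coef(qr(X), as.vector(patch)), error = function(e) c(1, 0))
    sum((as.vector(patch) - X %*% cf)^2)
  }
  side <- nrow(patch)
  fit <- optim(par0, obj, method = "L-BFGS-B",
               lower = c(0, 0, log(0.3), log(0.3)),
               upper = c(side - 1, side - 1, log(side / 2), log(side / 2)),
               control = list(maxit = 200))
  par <- fit$par
  g <- exp(-((rows - par[1])^2 / (2 * exp(2 * par[3])) +
             (cols - par[2])^2 / (2 * exp(2 * par[4]))))
  cf <- qr.coef(qr(cbind(as.vector(g), 1)), as.vector(patch))
  c(sigmaRow = exp(par[3]), sigmaCol = exp(par[4]),
    centerRow = par[1], centerCol = par[2],
    amplitude = unname(cf[1]), offset = unname(cf[2]), rss = fit$value)
}

#' Moment summary of a template bank
#'
#' Intensity-weighted per-axis widths and eccentricity of every template;
#' used to compare a generated bank against its training bank.
#'
#' @param bank a [TemplateBank-class].
#' @return data.frame with columns `sdRow`, `sdCol`, `eccentricity`.
#' @export
bankMoments <- function(bank) {
  m <- t(vapply(bank@templates, function(tp) {
    s <- patchMoments(tp@patch)$sd
    c(s[1], s[2], max(s) / max(min(s), 1e-12))
  }, numeric(3)))
  data.frame(sdRow = m[, 1], sdCol = m[, 2], eccentricity = m[, 3])
}
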
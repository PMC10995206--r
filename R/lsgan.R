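# Least-squares GAN over microbubble templates: a transposed-style
# (upsample + conv) generator and a strided-style (conv + pool) dense-headed
# discriminator, trained with least-squares adversarial losses. Replacing
# the sigmoid cross-entropy of the classic GAN with least squares stabilizes
# training and reduces mode collapse on small template sets.

ganInternalSide <- function(side) as.integer(4 * ceiling(side / 4))

#' Build an untrained LSGAN pair for template synthesis
#'
#' Generator: latent vector -> dense -> (f, S/4, S/4) feature map -> two
#' (upsample x2, 3x3 conv, ELU) blocks -> 1-channel softplus output cropped
#' to `side` (S is `side` rounded up to a multiple of 4). Discriminator:
#' two (3x3 conv, ELU, 2x2 max-pool) blocks -> dense scalar score.
#'
#' @param side template side length (odd; the generator works on the next
#'   multiple of 4 and centre-crops).
#' @param latentDim latent dimension (default 64).
#' @param genFilters,discFilters base channel widths.
#' @param seed optional integer seed for initialization.
#' @return a [GanModels-class] (untrained).
#' @export
buildLSGAN <- function(side = 65L, latentDim = 64L, genFilters = 16L,
                       discFilters = 8L, seed = NULL) {
  withSeed(seed, {
    S <- ganInternalSide(side)
    s0 <- S / 4L
    G <- list(
      fc = denseInit(latentDim, genFilters * s0 * s0),
      c1 = convInit(genFilters, genFilters),
      c2 = convInit(genFilters, genFilters),
      out = convInit(genFilters, 1L),
      meta = list(s0 = s0, f = genFilters, S = S)
    )
    # dark-background start: templates are sparse, so the softplus output
    # head opens from near zero
    G$out$b <- -3
    D <- list(
      c1 = convInit(1L, discFilters),
      c2 = convInit(discFilters, 2L * discFilters),
      fc = denseInit(2L * discFilters * s0 * s0, 1L),
      meta = list(s0 = s0, f = discFilters, S = S)
    )
    new("GanModels", generator = G, discriminator = D,
        latentDim = as.integer(latentDim), side = as.integer(side),
        trainingLog = data.frame(), muImax = 1, sigmaImax = 0)
  })
}

# generator forward: z is latentDim x N; returns S x S x N array (>= 0) and
# a cache for backprop
genForward <- function(G, z) {
  meta <- G$meta
  h0 <- denseFw(z, G$fc)                     # (f*s0*s0) x N
  a0 <- eluFw(h0)
  x0 <- array(a0, c(meta$f, meta$s0, meta$s0, ncol(z)))
  u1 <- cpp_upsample2(x0, dim(x0))
  c1 <- eluFw(convFw(u1, G$c1))
  u2 <- cpp_upsample2(c1, dim(c1))
  c2 <- eluFw(convFw(u2, G$c2))
  raw <- convFw(c2, G$out)                   # 1 x S x S x N
  out <- softplus(raw)
  dim(out) <- dim(raw)
  list(out = out, cache = list(z = z, h0 = h0, a0 = a0, x0 = x0, u1 = u1,
                               c1 = c1, u2 = u2, c2 = c2, raw = raw,
                               sp = out))
}

genBackward <- function(G, cache, dOut) {
  meta <- G$meta
  dRaw <- dOut * (-expm1(-cache$sp))
  dim(dRaw) <- dim(dOut)
  r1 <- convBw(cache$c2, G$out, dRaw)
  outG <- list(W = r1$dW, b = r1$db, k = 0)
  d2 <- eluBw(cache$c2, r1$dx)
  r2 <- convBw(cache$u2, G$c2, d2)
  c2G <- list(W = r2$dW, b = r2$db, k = 0)
  dc1 <- cpp_upsample2_bw(r2$dx, dim(cache$c1))
  d1 <- eluBw(cache$c1, dc1)
  r3 <- convBw(cache$u1, G$c1, d1)
  c1G <- list(W = r3$dW, b = r3$db, k = 0)
  dx0 <- cpp_upsample2_bw(r3$dx, dim(cache$x0))
  da0 <- matrix(dx0, meta$f * meta$s0 * meta$s0, ncol(cache$z))
  dh0 <- eluBw(matrix(cache$a0, nrow(da0)), da0)
  r4 <- denseBw(cache$z, G$fc, dh0)
  list(fc = list(W = r4$dW, b = r4$db), c1 = c1G, c2 = c2G, out = outG,
       meta = rapply(G$meta, function(x) 0, how = "replace"))
}

# discriminator forward: x is 1 x S x S x N; returns scores (length N)
discForward <- function(D, x) {
  c1 <- eluFw(convFw(x, D$c1))
  p1 <- cpp_maxpool(c1, dim(c1))
  c2 <- eluFw(convFw(p1$y, D$c2))
  p2 <- cpp_maxpool(c2, dim(c2))
  flat <- matrix(p2$y, length(p2$y) / dim(x)[4], dim(x)[4])
  score <- denseFw(flat, D$fc)
  list(score = as.numeric(score),
       cache = list(x = x, c1 = c1, p1 = p1, c2 = c2, p2 = p2, flat = flat))
}

# backward through D given dScore (length N); returns grads and dx
discBackward <- function(D, cache, dScore) {
  dS <- matrix(dScore, 1)
  r1 <- denseBw(cache$flat, D$fc, dS)
  fcG <- list(W = r1$dW, b = r1$db)
  dp2 <- array(r1$dx, dim(cache$p2$y))
  dc2 <- cpp_maxpool_bw(dp2, cache$p2$idx, dim(cache$c2))
  d2 <- eluBw(cache$c2, dc2)
  r2 <- convBw(cache$p1$y, D$c2, d2)
  c2G <- list(W = r2$dW, b = r2$db, k = 0)
  dp1 <- cpp_maxpool_bw(r2$dx, cache$p1$idx, dim(cache$c1))
  d1 <- eluBw(cache$c1, dp1)
  r3 <- convBw(cache$x, D$c1, d1)
  c1G <- list(W = r3$dW, b = r3$db, k = 0)
  list(grads = list(c1 = c1G, c2 = c2G, fc = fcG,
                    meta = rapply(D$meta, function(x) 0, how = "replace")),
       dx = r3$dx)
}

# embed a batch of side x side patches into the internal S x S canvas
padToCanvas <- function(patches, side, S) {
  N <- length(patches)
  x <- array(0, c(1, S, S, N))
  off <- floor((S - side) / 2)
  for (i in seq_len(N))
    x[1, off + seq_len(side), off + seq_len(side), i] <- patches[[i]]
  x
}

cropFromCanvas <- function(x4, side, S, n) {
  off <- floor((S - side) / 2)
  matrix(x4[1, off + seq_len(side), off + seq_len(side), n], side, side)
}

#' Train the least-squares GAN on a template bank
#'
#' Alternates one discriminator step and one generator step per batch. The
#' discriminator minimizes `0.5 E[(D(x) - 1)^2] + 0.5 E[D(G(z))^2]`; the
#' generator minimizes `0.5 E[(D(G(z)) - 1)^2]`. Epoch-mean losses for both
#' players are recorded in the training log. Deterministic for a fixed seed.
#'
#' @param bank a [TemplateBank-class] with at least `batch` templates.
#' @param epochs training epochs.
#' @param batch batch size (default 32).
#' @param latentDim latent dimension (default 64).
#' @param genFilters,discFilters channel widths.
#' @param lr generator Adam learning rate (default 2e-4).
#' @param lrD discriminator learning rate; the default `lr / 4` keeps the
#'   discriminator from overpowering the generator on small template sets.
#' @param seed integer seed.
#' @param verbose print per-epoch losses.
#' @return a trained [GanModels-class].
#' @export
trainLSGAN <- function(bank, epochs = 200, batch = 32L, latentDim = 64L,
                       genFilters = 16L, discFilters = 8L, lr = 2e-4,
                       lrD = lr / 4, seed = 1L, verbose = FALSE) {
  nT <- length(bank@templates)
  stopIfNot(nT >= batch, "bank must hold at least `batch` templates")
  side <- nrow(bank@templates[[1]]@patch)
  gan <- buildLSGAN(side, latentDim, genFilters, discFilters,
                    seed = deriveSeed(seed, "gan-init"))
  S <- ganInternalSide(side)
  patches <- lapply(bank@templates, function(t) t@patch)
  G <- gan@generator; D <- gan@discriminator
  stG <- adamInit(G); stD <- adamInit(D)
  logRows <- vector("list", epochs)
  step <- 0L
  set.seed(deriveSeed(seed, "gan-train"))
  nBatch <- max(1L, floor(nT / batch))
  for (ep in seq_len(epochs)) {
    perm <- sample.int(nT)
    dls <- gls <- numeric(nBatch)
    for (bi in seq_len(nBatch)) {
      ii <- perm[(bi - 1L) * batch + seq_len(batch)]
      xReal <- padToCanvas(patches[ii], side, S)
      # --- discriminator step ---
      z <- matrix(rnorm(latentDim * batch), latentDim)
      fake <- genForward(G, z)
      fr <- discForward(D, xReal)
      ff <- discForward(D, fake$out)
      lD <- 0.5 * mean((fr$score - 1)^2) + 0.5 * mean(ff$score^2)
      if (!is.finite(lD))
        stop(sprintf("LSGAN diverged (non-finite D loss, lr %g, epoch %d)",
                     lr, ep))
      gReal <- discBackward(D, fr$cache, (fr$score - 1) / batch)
      gFake <- discBackward(D, ff$cache, ff$score / batch)
      gD <- mapply(function(a, b) {
        if (is.list(a)) mapply(function(u, v) u + v, a, b, SIMPLIFY = FALSE)
        else a + b
      }, gReal$grads, gFake$grads, SIMPLIFY = FALSE)
      step <- step + 1L
      upD <- adamStep(D, gD, stD, lrD, step)
      D <- upD$params; stD <- upD$state
      # --- generator step ---
      z <- matrix(rnorm(latentDim * batch), latentDim)
      fake <- genForward(G, z)
      fg <- discForward(D, fake$out)
      lG <- 0.5 * mean((fg$score - 1)^2)
      if (!is.finite(lG))
        stop(sprintf("LSGAN diverged (non-finite G loss, lr %g, epoch %d)",
                     lr, ep))
      bw <- discBackward(D, fg$cache, (fg$score - 1) / batch)
      gG <- genBackward(G, fake$cache, bw$dx)
      upG <- adamStep(G, gG, stG, lr, step)
      G <- upG$params; stG <- upG$state
      dls[bi] <- lD; gls[bi] <- lG
    }
    logRows[[ep]] <- data.frame(epoch = ep, lossD = mean(dls),
                                lossG = mean(gls))
    if (verbose)
      message(sprintf("epoch %d: L(D) %.4f  L(G) %.4f", ep, mean(dls),
                      mean(gls)))
  }
  gan@generator <- G
  gan@discriminator <- D
  gan@trainingLog <- do.call(rbind, logRows)
  gan@muImax <- bank@muImax
  gan@sigmaImax <- bank@sigmaImax
  gan
}

#' Least-squares adversarial losses for given scores
#'
#' Plain evaluation of the two LSGAN objectives from discriminator scores;
#' exposed for testing and monitoring.
#'
#' @param realScores D(x) on real templates.
#' @param fakeScores D(G(z)) on generated templates.
#' @return named vector `lossD`, `lossG`.
#' @export
lsganLosses <- function(realScores, fakeScores) {
  c(lossD = 0.5 * mean((realScores - 1)^2) + 0.5 * mean(fakeScores^2),
    lossG = 0.5 * mean((fakeScores - 1)^2))
}

#' Sample templates from a trained generator
#'
#' Draws latent vectors, clamps the generated patches at zero, renormalizes
#' each to unit peak, and banks them with the brightness statistics of the
#' training bank (brightness is modelled separately by the simulator). An
#' all-zero patch is resampled with the next latent draw (at most 10 retries).
#'
#' @param gan a trained [GanModels-class].
#' @param n number of templates (>= 1).
#' @param seed integer seed.
#' @return a [TemplateBank-class] with `source = "lsgan"`.
#' @export
sampleTemplates <- function(gan, n, seed = 1L) {
  stopIfNot(n >= 1, "n must be >= 1")
  side <- gan@side
  S <- ganInternalSide(side)
  withSeed(seed, {
    tmpl <- vector("list", n)
    for (i in seq_len(n)) {
      patch <- NULL
      for (try in seq_len(10L)) {
        z <- matrix(rnorm(gan@latentDim), gan@latentDim)
        out <- genForward(gan@generator, z)$out
        p <- pmax(cropFromCanvas(out, side, S, 1), 0)
        if (max(p) > 1e-12) { patch <- p / max(p); break }
      }
      if (is.null(patch))
        stop("generator produced only all-zero patches (10 retries)")
      # centre the template reference on its argmax so the bank invariant
      # (peak within one pixel of centre + offset) holds by construction
      am <- which(patch == max(patch), arr.ind = TRUE)[1, ] - 1
      ctr <- (side - 1) / 2
      tmpl[[i]] <- new("MBTemplate", patch = patch, peakOffset = am - ctr)
    }
    new("TemplateBank", templates = tmpl, muImax = gan@muImax,
        sigmaImax = gan@sigmaImax, source = "lsgan")
  })
}
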
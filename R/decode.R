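# Context-aware probabilistic localization network: architecture, joint
# count + Gaussian-mixture localization loss (with analytic gradients),
# training on freshly simulated data, sliding-window inference, and
# post-processing of the probability maps into discrete localizations.

#' DecodeOutput: per-pixel channel maps of the localization network
#'
#' Nine channels for the centre frame of each three-frame window: detection
#' probability `p` in `[0,1]`; sub-pixel offsets `dRow`/`dCol` in
#' `(-0.5, 0.5)` input pixels; brightness `I`; uncertainties `sigmaRow`,
#' `sigmaCol`, `sigmaI` (strictly positive, floored); background mean `B`
#' and background uncertainty `sigmaB` (the background term of the loss is
#' identically zero because background noise is modelled separately, so the
#' last two channels are carried for architectural parity but unused).
#'
#' @slot p,dRow,dCol,I,sigmaRow,sigmaCol,sigmaI,B,sigmaB numeric matrices of
#'   identical shape.
#' @exportClass DecodeOutput
setClass("DecodeOutput",
  representation(p = "matrix", dRow = "matrix", dCol = "matrix", I = "matrix",
                 sigmaRow = "matrix", sigmaCol = "matrix", sigmaI = "matrix",
                 B = "matrix", sigmaB = "matrix")
)

setValidity("DecodeOutput", function(object) {
  msgs <- character()
  if (any(object@p < 0 | object@p > 1)) msgs <- c(msgs, "p must lie in [0,1]")
  if (any(abs(object@dRow) >= 0.5) || any(abs(object@dCol) >= 0.5))
    msgs <- c(msgs, "offsets must lie in (-0.5, 0.5)")
  if (any(object@sigmaRow <= 0) || any(object@sigmaCol <= 0) ||
      any(object@sigmaI <= 0))
    msgs <- c(msgs, "sigma channels must be strictly positive")
  if (length(msgs)) msgs else TRUE
})

SIGMA_FLOOR <- 0.01
COUNT_VAR_FLOOR <- 1e-6

#' Build the context-aware localization network
#'
#' A frame-analysis U-Net (applied to each of three consecutive frames; by
#' default with shared weights, optionally three separate stems) followed by
#' a temporal-context U-Net over the concatenated feature maps, and a 1x1
#' output head emitting the nine [DecodeOutput-class] channels for the
#' centre frame. All convolutions are 3x3 with ELU activations; each U-Net
#' has two downsampling/upsampling levels with channel widths
#' (f, 2f, 4f), f = `baseFilters`.
#'
#' @param baseFilters base channel width f (the reference configuration uses
#'   48; smaller values give proportionally cheaper desk-scale models).
#' @param sharedStem logical; share the frame-analysis weights across the
#'   three frames (default) or keep three separate stems.
#' @param seed optional integer seed for weight initialization.
#' @return a [DecodeModel-class] (untrained).
#' @export
buildDecodeNetwork <- function(baseFilters = 48L, sharedStem = TRUE,
                               seed = NULL) {
  withSeed(seed, {
    f <- as.integer(baseFilters)
    frame <- if (sharedStem) unetInit(1L, f) else
      list(unetInit(1L, f), unetInit(1L, f), unetInit(1L, f))
    context <- unetInit(3L * f, f)
    head <- convInit(f, 9L, k = 1)
    # start with a low detection probability, unit-scale sigmas/brightness
    head$b <- c(-4, 0, 0, inverseSoftplus(1), inverseSoftplus(1),
                inverseSoftplus(1), inverseSoftplus(0.5), inverseSoftplus(0.1),
                inverseSoftplus(0.1))
    new("DecodeModel",
        params = list(frame = frame, context = context, head = head),
        arch = list(baseFilters = f, sharedStem = isTRUE(sharedStem)),
        trainLog = data.frame())
  })
}

# channel order in the raw head output
CH <- list(p = 1L, dRow = 2L, dCol = 3L, I = 4L, sRow = 5L, sCol = 6L,
           sI = 7L, B = 8L, sB = 9L)

# squash raw head channels [9, H, W, N] into constrained outputs
squashHead <- function(raw) {
  out <- raw
  out[1, , , ] <- plogis(raw[1, , , ])
  out[2, , , ] <- 0.5 * tanh(raw[2, , , ])
  out[3, , , ] <- 0.5 * tanh(raw[3, , , ])
  for (ch in 4:9) out[ch, , , ] <- softplus(raw[ch, , , ])
  for (ch in 5:7) out[ch, , , ] <- out[ch, , , ] + SIGMA_FLOOR
  out
}

# gradient of the squash: dRaw given dOut and the squashed values
squashHeadBw <- function(out, dOut) {
  dRaw <- dOut
  p <- out[1, , , ]
  dRaw[1, , , ] <- dOut[1, , , ] * p * (1 - p)
  for (ch in 2:3)
    dRaw[ch, , , ] <- dOut[ch, , , ] * (0.5 - 2 * out[ch, , , ]^2)
  for (ch in 4:9) {
    s <- out[ch, , , ]
    if (ch %in% 5:7) s <- s - SIGMA_FLOOR
    dRaw[ch, , , ] <- dOut[ch, , , ] * (-expm1(-s))
  }
  dRaw
}

# forward pass over a batch of 3-frame windows: x is [H, W, 3, N]
decodeForward <- function(model, x, wantCache = FALSE) {
  P <- model@params
  H <- dim(x)[1]; W <- dim(x)[2]; N <- dim(x)[4]
  stopIfNot(dim(x)[3] == 3, "input windows must hold 3 consecutive frames")
  stopIfNot(H %% 4 == 0 && W %% 4 == 0,
            "frame size must be divisible by 4")
  f <- model@arch$baseFilters
  if (model@arch$sharedStem) {
    xb <- array(aperm(x, c(1, 2, 3, 4)), c(1, H, W, 3 * N))
    fr <- unetFw(xb, P$frame)
    feat <- fr$out  # [f, H, W, 3N]
    cat3 <- array(feat, c(f, H, W, 3, N))
    cat3 <- aperm(cat3, c(1, 4, 2, 3, 5))
    dim(cat3) <- c(3 * f, H, W, N)
    frCache <- fr$cache
  } else {
    feats <- lapply(1:3, function(t) {
      xt <- array(x[, , t, ], c(1, H, W, N))
      unetFw(xt, P$frame[[t]])
    })
    cat3 <- array(0, c(3 * f, H, W, N))
    for (t in 1:3) cat3[(t - 1) * f + seq_len(f), , , ] <- feats[[t]]$out
    frCache <- lapply(feats, `[[`, "cache")
  }
  ctx <- unetFw(cat3, P$context)
  raw <- convFw(ctx$out, P$head)
  out <- squashHead(raw)
  res <- list(out = out)
  if (wantCache)
    res$cache <- list(frame = frCache, context = ctx$cache, cat3 = cat3,
                      ctxOut = ctx$out, squashed = out, H = H, W = W, N = N)
  res
}

decodeBackward <- function(model, cache, dOut) {
  P <- model@params
  f <- model@arch$baseFilters
  H <- cache$H; W <- cache$W; N <- cache$N
  dRaw <- squashHeadBw(cache$squashed, dOut)
  hb <- convBw(cache$ctxOut, P$head, dRaw)
  headG <- list(W = hb$dW, b = hb$db, k = 0)
  ctxB <- unetBw(hb$dx, P$context, cache$context)
  dcat <- ctxB$dx  # [3f, H, W, N]
  if (model@arch$sharedStem) {
    dfeat <- array(dcat, c(f, 3, H, W, N))
    dfeat <- aperm(dfeat, c(1, 3, 4, 2, 5))
    dim(dfeat) <- c(f, H, W, 3 * N)
    frB <- unetBw(dfeat, P$frame, cache$frame)
    frameG <- frB$grads
  } else {
    frameG <- vector("list", 3)
    for (t in 1:3) {
      dfe <- dcat[(t - 1) * f + seq_len(f), , , , drop = FALSE]
      frB <- unetBw(dfe, P$frame[[t]], cache$frame[[t]])
      frameG[[t]] <- frB$grads
    }
  }
  list(frame = frameG, context = ctxB$grads, head = headG)
}

#' Count loss: Gaussian approximation of the Poisson-binomial count
#'
#' With per-pixel detection probabilities `p`, the predicted bubble count is
#' Poisson-binomial with mean `mu = sum(p)` and variance
#' `sigma2 = sum(p (1 - p))`; for many pixels this approximates a Gaussian,
#' and the negative log-likelihood of the true count `E` is
#' `(E - mu)^2 / (2 sigma2) + log(sqrt(2 pi) sigma)`. The variance is floored
#' at 1e-6 so saturated probability maps stay finite.
#'
#' @param p vector or matrix of detection probabilities in `[0,1]`.
#' @param E true bubble count.
#' @return scalar loss.
#' @examples
#' countLoss(rep(0.5, 4), 2)  # log(sqrt(2*pi)) ~ 0.9189
#' @export
countLoss <- function(p, E) {
  mu <- sum(p)
  s2 <- sum(p * (1 - p)) + COUNT_VAR_FLOOR
  0.5 * (E - mu)^2 / s2 + log(sqrt(2 * pi * s2))
}

# gradient of countLoss w.r.t. p (same shape as p)
countLossGrad <- function(p, E) {
  mu <- sum(p)
  s2 <- sum(p * (1 - p)) + COUNT_VAR_FLOOR
  dmu <- -(E - mu) / s2
  ds2 <- -0.5 * (E - mu)^2 / s2^2 + 0.5 / s2
  dmu + ds2 * (1 - 2 * p)
}

#' Localization loss: Gaussian-mixture likelihood of the ground truth
#'
#' Every pixel contributes a mixture component with weight
#' `w_k = p_k / sum(p)`, mean `(row_k + dRow_k, col_k + dCol_k, I_k)` and
#' diagonal covariance `(sigmaRow_k^2, sigmaCol_k^2, sigmaI_k^2)`. The loss
#' is the negative mean log-likelihood of the `E` ground-truth bubbles
#' (position in output-grid pixels and brightness) under this 3-D mixture,
#' computed with log-sum-exp.
#'
#' @param out a [DecodeOutput-class].
#' @param gt data.frame with columns `row`, `col` (output-grid pixel
#'   coordinates, 0-based) and `brightness`; at least one row.
#' @return scalar loss.
#' @export
localizationLoss <- function(out, gt) {
  locLossCore(out, gt, wantGrad = FALSE)$loss
}

# shared loss/gradient computation; channels as matrices (H x W)
locLossCore <- function(out, gt, wantGrad = TRUE) {
  stopIfNot(nrow(gt) >= 1, "localization loss needs at least one GT bubble")
  p <- as.vector(out@p)
  sp <- sum(p)
  if (sp <= 0) stop("all detection probabilities are zero (no mixture support)")
  H <- nrow(out@p); W <- ncol(out@p)
  K <- H * W; E <- nrow(gt)
  muR <- as.vector(row(out@p) - 1 + out@dRow)
  muC <- as.vector(col(out@p) - 1 + out@dCol)
  muI <- as.vector(out@I)
  sR <- as.vector(out@sigmaRow); sC <- as.vector(out@sigmaCol)
  sI <- as.vector(out@sigmaI)
  logNorm <- -(1.5 * log(2 * pi) + log(sR) + log(sC) + log(sI))
  # E x K matrices of standardized residuals
  zR <- outer(gt$row, muR, "-") / rep(sR, each = E)
  zC <- outer(gt$col, muC, "-") / rep(sC, each = E)
  zI <- outer(gt$brightness, muI, "-") / rep(sI, each = E)
  logN <- -0.5 * (zR^2 + zC^2 + zI^2) + rep(logNorm, each = E)
  logw <- log(pmax(p, 1e-300)) - log(sp)
  lse <- rowLogSumExp(sweep(logN, 2, logw, "+"))
  loss <- -mean(lse)
  if (!wantGrad) return(list(loss = loss))
  gam <- exp(sweep(logN, 2, logw, "+") - lse)       # responsibilities, E x K
  Tk <- colSums(exp(logN - lse))                     # sum_e N_ek / mix_e
  Sk <- colSums(gam)
  dMuR <- -colSums(gam * zR / rep(sR, each = E)) / E
  dMuC <- -colSums(gam * zC / rep(sC, each = E)) / E
  dMuI <- -colSums(gam * zI / rep(sI, each = E)) / E
  dSR <- -colSums(gam * (zR^2 - 1)) / (E * sR)
  dSC <- -colSums(gam * (zC^2 - 1)) / (E * sC)
  dSI <- -colSums(gam * (zI^2 - 1)) / (E * sI)
  dP <- (1 - Tk / E) / sp
  shape <- function(v) matrix(v, H, W)
  list(loss = loss,
       grad = list(p = shape(dP), dRow = shape(dMuR), dCol = shape(dMuC),
                   I = shape(dMuI), sigmaRow = shape(dSR),
                   sigmaCol = shape(dSC), sigmaI = shape(dSI)))
}

#' Total training loss for one frame
#'
#' Count loss plus (for frames containing at least one bubble) the
#' Gaussian-mixture localization loss. The background loss is identically
#' zero because background noise is modelled separately by the simulator.
#'
#' @param out a [DecodeOutput-class].
#' @param gt ground-truth data.frame (`row`, `col`, `brightness`), possibly
#'   empty.
#' @return scalar loss.
#' @export
totalLoss <- function(out, gt) {
  l <- countLoss(out@p, nrow(gt))
  if (nrow(gt) > 0) l <- l + localizationLoss(out, gt)
  l
}

# slice one sample of the squashed head output into a DecodeOutput
sliceOutput <- function(out4, n) {
  m <- function(ch) matrix(out4[ch, , , n], dim(out4)[2], dim(out4)[3])
  new("DecodeOutput", p = m(1), dRow = m(2), dCol = m(3), I = m(4),
      sigmaRow = m(5), sigmaCol = m(6), sigmaI = m(7), B = m(8), sigmaB = m(9))
}

# loss + gradient w.r.t. the squashed channels for a batch; gts is a list of
# GT data.frames (output-grid coords). Returns mean loss and dOut [9,H,W,N].
batchLossGrad <- function(out4, gts) {
  H <- dim(out4)[2]; W <- dim(out4)[3]; N <- dim(out4)[4]
  dOut <- array(0, dim(out4))
  total <- 0
  for (n in seq_len(N)) {
    o <- sliceOutput(out4, n)
    E <- nrow(gts[[n]])
    total <- total + countLoss(o@p, E)
    dP <- countLossGrad(o@p, E)
    if (E > 0) {
      lc <- locLossCore(o, gts[[n]])
      total <- total + lc$loss
      dP <- dP + lc$grad$p
      dOut[2, , , n] <- lc$grad$dRow
      dOut[3, , , n] <- lc$grad$dCol
      dOut[4, , , n] <- lc$grad$I
      dOut[5, , , n] <- lc$grad$sigmaRow
      dOut[6, , , n] <- lc$grad$sigmaCol
      dOut[7, , , n] <- lc$grad$sigmaI
    }
    dOut[1, , , n] <- dP
  }
  list(loss = total / N, dOut = dOut / N)
}

#' Train the localization network on freshly simulated data
#'
#' Every training sample is a freshly simulated three-frame window (no frame
#' is ever reused), drawn at a concentration sampled uniformly from
#' `concentrationRange`; ground truth for the centre frame is mapped to the
#' network input grid. Optimization is Adam with the learning rate halved
#' when the epoch-mean loss stops improving; gradients are clipped by global
#' norm. Deterministic for a fixed seed.
#'
#' @param cfg an [ImagingConfig-class].
#' @param bank a [TemplateBank-class].
#' @param noiseModel a [NoiseModel-class] on the input grid (or NULL).
#' @param epochs number of epochs.
#' @param framesPerEpoch simulated training windows per epoch (the reference
#'   regime uses 10000; desk-scale runs use less).
#' @param concentrationRange range of training concentrations (MBs/lambda^2).
#' @param baseFilters base channel width of the network.
#' @param batchSize windows per optimization step.
#' @param lr initial Adam learning rate.
#' @param clipNorm global gradient-norm clip.
#' @param seed integer seed (weights, simulation and shuffling).
#' @param verbose print per-epoch losses.
#' @return a trained [DecodeModel-class] with a `trainLog`.
#' @export
trainDecode <- function(cfg, bank, noiseModel = NULL, epochs = 5,
                        framesPerEpoch = 2000, concentrationRange = c(0.02, 0.4),
                        baseFilters = 16L, batchSize = 16L, lr = 6e-4,
                        clipNorm = 50, seed = 1L, verbose = FALSE) {
  model <- buildDecodeNetwork(baseFilters, seed = deriveSeed(seed, "init"))
  state <- adamInit(model@params)
  H <- cfg@fovFine[1] / cfg@downsample
  W <- cfg@fovFine[2] / cfg@downsample
  d <- cfg@downsample
  log <- data.frame(epoch = integer(), loss = numeric(), lr = numeric())
  step <- 0L
  best <- Inf
  curLr <- lr
  for (ep in seq_len(epochs)) {
    set.seed(deriveSeed(seed, paste0("epoch", ep)))
    nBatch <- ceiling(framesPerEpoch / batchSize)
    epLoss <- 0
    for (bi in seq_len(nBatch)) {
      nb <- min(batchSize, framesPerEpoch - (bi - 1L) * batchSize)
      x <- array(0, c(H, W, 3, nb))
      gts <- vector("list", nb)
      for (s in seq_len(nb)) {
        conc <- runif(1, concentrationRange[1], concentrationRange[2])
        states <- initPopulation(cfg, conc, bank)
        for (t in 1:3) {
          rf <- renderFrame(states, bank, cfg)
          fr <- rf$frame
          if (!is.null(noiseModel)) fr <- addRicianNoise(fr, noiseModel)
          x[, , t, s] <- fr
          if (t == 2)
            gts[[s]] <- data.frame(
              row = fineToInput(rf$gt$row, d),
              col = fineToInput(rf$gt$col, d),
              brightness = rf$gt$brightness
            )
          states <- stepMotion(states, cfg, bank)
        }
      }
      fw <- decodeForward(model, x, wantCache = TRUE)
      bl <- batchLossGrad(fw$out, gts)
      grads <- decodeBackward(model, fw$cache, bl$dOut)
      grads <- clipGrads(grads, clipNorm)
      step <- step + 1L
      upd <- adamStep(model@params, grads, state, curLr, step)
      model@params <- upd$params
      state <- upd$state
      epLoss <- epLoss + bl$loss * nb
      if (!is.finite(bl$loss))
        stop(sprintf("training diverged (non-finite loss, epoch %d, lr %g)",
                     ep, curLr))
    }
    epLoss <- epLoss / framesPerEpoch
    if (epLoss > best - 1e-3) curLr <- curLr / 2 else best <- min(best, epLoss)
    log <- rbind(log, data.frame(epoch = ep, loss = epLoss, lr = curLr))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f (lr %.2g)", ep, epLoss, curLr))
  }
  model@trainLog <- log
  model
}

#' Sliding-window inference
#'
#' Applies the network to every window of three consecutive frames and
#' returns one [DecodeOutput-class] per interior frame (`t = 2 .. T-1`,
#' 1-based); the first and last frames have no output.
#'
#' @param model a trained [DecodeModel-class].
#' @param stack a [FrameStack-class] with at least 3 frames.
#' @param batchSize windows per forward pass.
#' @return list of [DecodeOutput-class], one per interior frame.
#' @export
decodeInfer <- function(model, stack, batchSize = 32L) {
  dat <- stack@data
  T <- dim(dat)[1]
  stopIfNot(T >= 3, "need at least 3 frames for temporal context")
  H <- dim(dat)[2]; W <- dim(dat)[3]
  outs <- vector("list", T - 2L)
  idx <- seq_len(T - 2L)
  for (chunk in split(idx, ceiling(idx / batchSize))) {
    x <- array(0, c(H, W, 3, length(chunk)))
    for (j in seq_along(chunk)) {
      t0 <- chunk[j]
      x[, , 1, j] <- dat[t0, , ]
      x[, , 2, j] <- dat[t0 + 1, , ]
      x[, , 3, j] <- dat[t0 + 2, , ]
    }
    fw <- decodeForward(model, x)
    for (j in seq_along(chunk)) outs[[chunk[j]]] <- sliceOutput(fw$out, j)
  }
  outs
}

#' Post-process a probability map into discrete localizations
#'
#' Candidate pixels are local maxima of `p` within a
#' `(2 aggRadius + 1)^2` window whose neighbourhood-summed probability
#' reaches `pThresh` (the per-pixel Bernoulli field is aggregated into
#' per-bubble probability mass). Each candidate becomes a localization at
#' pixel centre plus predicted sub-pixel offset, with the predicted
#' brightness and uncertainties; finally the fraction
#' `uncertaintyRejectFrac` with the largest positional uncertainty
#' `sqrt(sigmaRow^2 + sigmaCol^2)` is discarded.
#'
#' @param out a [DecodeOutput-class].
#' @param pThresh neighbourhood probability threshold (default 0.6).
#' @param aggRadius aggregation radius in pixels (default 1).
#' @param uncertaintyRejectFrac fraction of highest-uncertainty detections to
#'   reject (default 0.05).
#' @return data.frame `row`, `col` (continuous output-grid px), `brightness`,
#'   `prob`, `sigmaRow`, `sigmaCol`, `sigmaI`.
#' @export
decodeDetections <- function(out, pThresh = 0.6, aggRadius = 1L,
                             uncertaintyRejectFrac = 0.05) {
  p <- out@p
  H <- nrow(p); W <- ncol(p)
  r <- aggRadius
  pad <- matrix(-Inf, H + 2 * r, W + 2 * r)
  pad[r + seq_len(H), r + seq_len(W)] <- p
  psum <- matrix(0, H, W)
  pmaxn <- matrix(-Inf, H, W)
  for (dr in -r:r) for (dc in -r:r) {
    sh <- pad[r + dr + seq_len(H), r + dc + seq_len(W)]
    pmaxn <- pmax(pmaxn, sh)
    psum <- psum + pmax(sh, 0) * is.finite(sh)
  }
  cand <- which(p >= pmaxn & psum >= pThresh, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(row = numeric(), col = numeric(),
                      brightness = numeric(), prob = numeric(),
                      sigmaRow = numeric(), sigmaCol = numeric(),
                      sigmaI = numeric()))
  i <- cand[, 1]; j <- cand[, 2]
  ind <- cbind(i, j)
  det <- data.frame(
    row = i - 1 + out@dRow[ind],
    col = j - 1 + out@dCol[ind],
    brightness = out@I[ind],
    prob = pmin(psum[ind], 1),
    sigmaRow = out@sigmaRow[ind],
    sigmaCol = out@sigmaCol[ind],
    sigmaI = out@sigmaI[ind]
  )
  if (uncertaintyRejectFrac > 0 && nrow(det) > 0) {
    u <- sqrt(det$sigmaRow^2 + det$sigmaCol^2)
    nRej <- floor(uncertaintyRejectFrac * nrow(det))
    if (nRej > 0) det <- det[order(u)[seq_len(nrow(det) - nRej)], , drop = FALSE]
  }
  rownames(det) <- NULL
  det
}

#' Run inference over a stack and collect localizations
#'
#' Convenience wrapper chaining [decodeInfer()] and [decodeDetections()];
#' coordinates are returned on the fine grid.
#'
#' @inheritParams decodeInfer
#' @inheritParams decodeDetections
#' @return data.frame with `frame` (0-based, interior frames only), fine-grid
#'   `row`, `col`, plus brightness/probability/uncertainty columns.
#' @export
decodeLocalize <- function(model, stack, pThresh = 0.6, aggRadius = 1L,
                           uncertaintyRejectFrac = 0.05, batchSize = 32L) {
  outs <- decodeInfer(model, stack, batchSize)
  d <- stack@config@downsample
  res <- lapply(seq_along(outs), function(k) {
    det <- decodeDetections(outs[[k]], pThresh, aggRadius,
                            uncertaintyRejectFrac)
    if (nrow(det) == 0) return(NULL)
    det$row <- inputToFine(det$row, d)
    det$col <- inputToFine(det$col, d)
    cbind(frame = k, det)  # window k has centre frame k (0-based frame index)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(frame = integer(), row = numeric(), col = numeric(),
                      brightness = numeric(), prob = numeric(),
                      sigmaRow = numeric(), sigmaCol = numeric(),
                      sigmaI = numeric())
  res
}
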
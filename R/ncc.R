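# Conventional baseline localizer: zero-normalized cross-correlation against
# a bivariate Gaussian template, regional maximum search with distance
# suppression, and sub-pixel refinement.

#' Zero-normalized cross-correlation map
#'
#' ZNCC of the frame against the template at every displacement where the
#' template fully fits; border positions are filled with -1. The map is
#' invariant to positive affine intensity transforms of the frame.
#'
#' @param frame numeric matrix.
#' @param template an [MBTemplate-class] or plain matrix, strictly smaller
#'   than the frame.
#' @return matrix of correlations in `[-1, 1]`, same size as the frame.
#' @export
nccMap <- function(frame, template) {
  tp <- if (is(template, "MBTemplate")) template@patch else template
  stopIfNot(nrow(tp) < nrow(frame) && ncol(tp) < ncol(frame),
            "template must be smaller than the frame")
  cpp_ncc_map(frame, tp, -1)
}

#' Regional maximum search with distance suppression
#'
#' Strict local maxima (8-neighbourhood) above `threshold`, greedily
#' suppressed within `minDistance` pixels: higher values win, ties are broken
#' in row-major order.
#'
#' @param map correlation (or intensity) matrix.
#' @param threshold minimum value for a peak.
#' @param minDistance minimum Chebyshev-Euclidean distance between surviving
#'   peaks (Euclidean, in pixels).
#' @return integer matrix of 0-based (row, col) peak positions, one row per
#'   peak, ordered by decreasing map value.
#' @export
findPeaks <- function(map, threshold = 0.6, minDistance = 3L) {
  H <- nrow(map); W <- ncol(map)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[1 + seq_len(H), 1 + seq_len(W)] <- map
  isMax <- map > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    isMax <- isMax & (map > pad[1 + dr + seq_len(H), 1 + dc + seq_len(W)])
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(integer(), 0, 2,
                                    dimnames = list(NULL, c("row", "col"))))
  vals <- map[idx]
  ord <- order(-vals, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    ok <- TRUE
    if (any(keep)) {
      kept <- idx[keep, , drop = FALSE]
      d2 <- (kept[, 1] - idx[i, 1])^2 + (kept[, 2] - idx[i, 2])^2
      ok <- all(d2 >= minDistance^2)
    }
    keep[i] <- ok
  }
  out <- idx[keep, , drop = FALSE] - 1L
  colnames(out) <- c("row", "col")
  out
}

#' Sub-pixel refinement of integer peaks
#'
#' `paraboloid` mode fits a 2-D quadratic to the 3x3 neighbourhood of the
#' correlation surface and returns its vertex, clamped to +/- 0.5 px;
#' `centroid` mode returns the intensity-weighted centroid of the 5x5
#' neighbourhood. Peaks on the border are returned unrefined with
#' `refined = FALSE`.
#'
#' @param map matrix to refine on (correlation map or frame).
#' @param peaks integer matrix of 0-based (row, col) peaks.
#' @param refine "paraboloid" or "centroid".
#' @return data.frame `row`, `col` (continuous, 0-based), `value`, `refined`.
#' @export
subpixelRefine <- function(map, peaks, refine = c("paraboloid", "centroid")) {
  refine <- match.arg(refine)
  H <- nrow(map); W <- ncol(map)
  n <- nrow(peaks)
  res <- data.frame(row = numeric(n), col = numeric(n), value = numeric(n),
                    refined = logical(n))
  rad <- if (refine == "paraboloid") 1L else 2L
  for (i in seq_len(n)) {
    r <- peaks[i, 1] + 1L; c <- peaks[i, 2] + 1L  # 1-based
    res$value[i] <- map[r, c]
    if (r - rad < 1 || r + rad > H || c - rad < 1 || c + rad > W) {
      res$row[i] <- r - 1; res$col[i] <- c - 1; res$refined[i] <- FALSE
      next
    }
    nb <- map[(r - rad):(r + rad), (c - rad):(c + rad)]
    if (refine == "paraboloid") {
      off <- paraboloidVertex(nb)
    } else {
      w <- pmax(nb, 0)
      s <- sum(w)
      off <- if (s > 0)
        c(sum((row(nb) - rad - 1) * w), sum((col(nb) - rad - 1) * w)) / s
      else c(0, 0)
    }
    off <- pmin(pmax(off, -0.5), 0.5)
    res$row[i] <- r - 1 + off[1]
    res$col[i] <- c - 1 + off[2]
    res$refined[i] <- TRUE
  }
  res
}

# least-squares quadratic a + b x + c y + d x^2 + e y^2 + f xy on the 3x3
# neighbourhood (x = row offset, y = col offset in -1..1); returns the vertex
paraboloidVertex <- function(nb) {
  x <- as.vector(row(nb)) - 2
  y <- as.vector(col(nb)) - 2
  z <- as.vector(nb)
  X <- cbind(1, x, y, x^2, y^2, x * y)
  beta <- solve(crossprod(X), crossprod(X, z))
  A <- matrix(c(2 * beta[4], beta[6], beta[6], 2 * beta[5]), 2)
  if (abs(det(A)) < 1e-12) return(c(0, 0))
  v <- -solve(A, beta[2:3])
  as.numeric(v)
}

#' Conventional localization of a frame stack
#'
#' Runs [nccMap()], [findPeaks()] and [subpixelRefine()] on every frame.
#'
#' @param stack a [FrameStack-class].
#' @param template matching template (defaults to a bivariate Gaussian whose
#'   SD is 2 fine pixels expressed on the stack's grid).
#' @param nccThreshold correlation threshold in (0, 1).
#' @param minDistance peak suppression distance (px).
#' @param refine sub-pixel mode.
#' @param fineCoords return coordinates on the fine grid (default) rather
#'   than the stack's own grid.
#' @return data.frame `frame` (0-based), `row`, `col`, `value`.
#' @export
nccLocalize <- function(stack, template = NULL, nccThreshold = 0.6,
                        minDistance = 3L, refine = "paraboloid",
                        fineCoords = TRUE) {
  cfg <- stack@config
  d <- if (stack@stage == "fine") 1L else cfg@downsample
  if (is.null(template)) {
    sig <- 2 / d  # 2 fine px expressed on this grid
    side <- max(2 * ceiling(3 * sig) + 1, 5)
    template <- makeGaussianTemplate(sig, sig, side = side)
  }
  tp <- if (is(template, "MBTemplate")) template@patch else template
  res <- lapply(seq_len(dim(stack@data)[1]), function(t) {
    fr <- stack@data[t, , ]
    m <- nccMap(fr, tp)
    pk <- findPeaks(m, nccThreshold, minDistance)
    if (nrow(pk) == 0) return(NULL)
    ref <- subpixelRefine(m, pk, refine)
    data.frame(frame = t - 1L, row = ref$row, col = ref$col,
               value = ref$value)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(frame = integer(), row = numeric(), col = numeric(),
                      value = numeric())
  if (fineCoords && d > 1) {
    res$row <- inputToFine(res$row, d)
    res$col <- inputToFine(res$col, d)
  }
  res
}
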
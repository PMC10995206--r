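# Internal numeric helpers shared across modules.

softplus <- function(x) {
  # log(1 + exp(x)) without overflow
  pmax(x, 0) + log1p(exp(-abs(x)))
}

inverseSoftplus <- function(y) {
  # a such that softplus(a) = y, y > 0
  y + log(-expm1(-y))
}

elu <- function(x) ifelse(x > 0, x, expm1(x))

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

rowLogSumExp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed and a stage tag, so that re-ordering or skipping stages does not
#' perturb the randomness of the others. Sub-seeds stay below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param tag character stage tag.
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 104729) %% 2147483647L)
}

withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# weighted first/second moments of a non-negative patch; returns centre of
# mass (row, col) and per-axis weighted SDs
patchMoments <- function(patch) {
  w <- pmax(patch, 0)
  s <- sum(w)
  if (s <= 0) return(list(com = c(NA_real_, NA_real_), sd = c(NA_real_, NA_real_)))
  rows <- row(patch) - 1
  cols <- col(patch) - 1
  cr <- sum(rows * w) / s
  cc <- sum(cols * w) / s
  sr <- sqrt(sum((rows - cr)^2 * w) / s)
  sc <- sqrt(sum((cols - cc)^2 * w) / s)
  list(com = c(cr, cc), sd = c(sr, sc))
}
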
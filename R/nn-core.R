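# Minimal dense-prediction network engine: same-padding 3x3 (and 1x1)
# convolutions via im2col + BLAS GEMM (src/conv.cpp), ELU activations,
# 2x2 max pooling, x2 nearest-neighbour upsampling, dense layers, and an
# Adam optimizer. Feature maps are arrays [C, H, W, N]. All backward passes
# are analytic and verified against numerical differentiation in the tests.

convInit <- function(cin, cout, k = 3) {
  list(W = matrix(rnorm(cout * cin * k * k, 0, sqrt(2 / (cin * k * k))),
                  nrow = cout),
       b = numeric(cout), k = k)
}

convFw <- function(x, p) {
  cpp_conv_fw(x, dim(x), p$W, p$b, p$k)
}

convBw <- function(x, p, dy) {
  cpp_conv_bw(x, dim(x), p$W, dy, p$k)
}

eluFw <- function(x) cpp_elu(x)

# derivative expressed through the activation value a = elu(x)
eluBw <- function(a, da) cpp_elu_bw(a, da)

denseInit <- function(nin, nout) {
  list(W = matrix(rnorm(nout * nin, 0, sqrt(2 / nin)), nrow = nout),
       b = numeric(nout))
}

denseFw <- function(x, p) p$W %*% x + p$b  # x: nin x N

denseBw <- function(x, p, dy) {
  list(dx = crossprod(p$W, dy), dW = tcrossprod(dy, x), db = rowSums(dy))
}

# ---- Adam ----

adamInit <- function(params) {
  rapply(params, function(x) list(m = x * 0, v = x * 0),
         how = "list", classes = "ANY")
}

adamStep <- function(params, grads, state, lr, t,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out <- mapply(walk, p, g, s, SIMPLIFY = FALSE)
      list(params = lapply(out, `[[`, "params"),
           state = lapply(out, `[[`, "state"))
    } else {
      m <- beta1 * s$m + (1 - beta1) * g
      v <- beta2 * s$v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(params = p - lr * mh / (sqrt(vh) + eps), state = list(m = m, v = v))
    }
  }
  walk(params, grads, state)
}

gradGlobalNorm <- function(grads) {
  sqrt(sum(vapply(rapply(grads, function(x) sum(x^2), how = "unlist"),
                  identity, numeric(1))))
}

clipGrads <- function(grads, maxNorm) {
  nrm <- gradGlobalNorm(grads)
  if (is.finite(nrm) && nrm > maxNorm)
    grads <- rapply(grads, function(x) x * (maxNorm / nrm), how = "replace")
  grads
}
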
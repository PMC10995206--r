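// Convolution primitives for the small dense-prediction networks used by
// the localization engine: same-padding stride-1 convolution organised as
// one GEMM per kernel tap over contiguous subcube copies (memory-friendly;
// no im2col materialisation), 2x2 max pooling, and x2 nearest-neighbour
// upsampling. Feature maps are R arrays with dims [C, H, W, N] (channel
// fastest). Weight matrices are [Cout, C*k*k] with column blocks ordered by
// tap (dw outer, dh inner) and channel fastest within a tap.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// gather the shifted input region for one tap across all samples into a
// C x (nh*nw*N) matrix (columns ordered h, w, n)
static void gatherTap(const double* x, int C, int H, int W, int N,
                      int hlo, int hhi, int wlo, int whi, arma::mat& buf) {
  const int nh = hhi - hlo + 1, nw = whi - wlo + 1;
  double* dst = buf.memptr();
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)n * C * H * W;
    for (int w = wlo; w <= whi; ++w) {
      const double* src = xn + ((size_t)w * H + hlo) * C;
      std::memcpy(dst, src, sizeof(double) * (size_t)C * nh);
      dst += (size_t)C * nh;
    }
  }
  (void)nw;
}

// scatter-add a Cout x (nh*nw*N) matrix into the output region of y
static void scatterTap(double* y, int C, int H, int W, int N,
                       int hlo, int hhi, int wlo, int whi,
                       const arma::mat& buf) {
  const int nh = hhi - hlo + 1;
  const double* src = buf.memptr();
  for (int n = 0; n < N; ++n) {
    double* yn = y + (size_t)n * C * H * W;
    for (int w = wlo; w <= whi; ++w) {
      double* dst = yn + ((size_t)w * H + hlo) * C;
      const size_t len = (size_t)C * nh;
      for (size_t i = 0; i < len; ++i) dst[i] += src[i];
      src += len;
    }
  }
}

// forward: y[Cout,H,W,N] = sum_taps W_tap %*% shift(x) + b
// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, IntegerVector dims,
                          NumericMatrix Wm, NumericVector b, int k) {
  const int C = dims[0], H = dims[1], Wd = dims[2], N = dims[3];
  const int pad = (k - 1) / 2, Cout = Wm.nrow();
  const size_t HWN = (size_t)H * Wd * N;
  NumericVector y(Cout * HWN);
  // bias fill
  {
    double* yp = y.begin();
    for (size_t i = 0; i < HWN; ++i)
      for (int c = 0; c < Cout; ++c) yp[i * Cout + c] = b[c];
  }
  arma::mat Wa(Wm.begin(), Cout, Wm.ncol(), false);
  arma::mat xbuf, ybuf;
  for (int dw = -pad; dw <= pad; ++dw) {
    for (int dh = -pad; dh <= pad; ++dh) {
      const int tap = (dw + pad) * k + (dh + pad);
      // output pixels (h,w) with input (h+dh, w+dw) in range
      const int ho0 = std::max(0, -dh), ho1 = std::min(H - 1, H - 1 - dh);
      const int wo0 = std::max(0, -dw), wo1 = std::min(Wd - 1, Wd - 1 - dw);
      if (ho0 > ho1 || wo0 > wo1) continue;
      const int nh = ho1 - ho0 + 1, nw = wo1 - wo0 + 1;
      xbuf.set_size(C, (size_t)nh * nw * N);
      gatherTap(x.begin(), C, H, Wd, N, ho0 + dh, ho1 + dh, wo0 + dw,
                wo1 + dw, xbuf);
      ybuf = Wa.cols((size_t)tap * C, (size_t)tap * C + C - 1) * xbuf;
      scatterTap(y.begin(), Cout, H, Wd, N, ho0, ho1, wo0, wo1, ybuf);
    }
  }
  y.attr("dim") = IntegerVector::create(Cout, H, Wd, N);
  return y;
}

// backward: dW_tap = dY_region * X_region', db = rowsum(dY),
// dX_region += W_tap' * dY_region
// [[Rcpp::export]]
List cpp_conv_bw(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                 NumericVector dy, int k) {
  const int C = dims[0], H = dims[1], Wd = dims[2], N = dims[3];
  const int pad = (k - 1) / 2, Cout = Wm.nrow();
  arma::mat Wa(Wm.begin(), Cout, Wm.ncol(), false);
  arma::mat dW(Cout, Wm.ncol(), arma::fill::zeros);
  NumericVector dx(x.size());
  arma::vec db(Cout, arma::fill::zeros);
  {
    const double* dyp = dy.begin();
    const size_t HWN = (size_t)H * Wd * N;
    for (size_t i = 0; i < HWN; ++i)
      for (int c = 0; c < Cout; ++c) db[c] += dyp[i * Cout + c];
  }
  arma::mat xbuf, dybuf, dxbuf;
  for (int dw = -pad; dw <= pad; ++dw) {
    for (int dh = -pad; dh <= pad; ++dh) {
      const int tap = (dw + pad) * k + (dh + pad);
      const int ho0 = std::max(0, -dh), ho1 = std::min(H - 1, H - 1 - dh);
      const int wo0 = std::max(0, -dw), wo1 = std::min(Wd - 1, Wd - 1 - dw);
      if (ho0 > ho1 || wo0 > wo1) continue;
      const int nh = ho1 - ho0 + 1, nw = wo1 - wo0 + 1;
      const size_t V = (size_t)nh * nw * N;
      xbuf.set_size(C, V);
      dybuf.set_size(Cout, V);
      gatherTap(x.begin(), C, H, Wd, N, ho0 + dh, ho1 + dh, wo0 + dw,
                wo1 + dw, xbuf);
      gatherTap(dy.begin(), Cout, H, Wd, N, ho0, ho1, wo0, wo1, dybuf);
      dW.cols((size_t)tap * C, (size_t)tap * C + C - 1) += dybuf * xbuf.t();
      dxbuf = Wa.cols((size_t)tap * C, (size_t)tap * C + C - 1).t() * dybuf;
      scatterTap(dx.begin(), C, H, Wd, N, ho0 + dh, ho1 + dh, wo0 + dw,
                 wo1 + dw, dxbuf);
    }
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx,
                      _["dW"] = NumericMatrix(Cout, Wm.ncol(), dW.begin()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, IntegerVector dims) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)C * Ho * Wo * N);
  IntegerVector idx((size_t)C * Ho * Wo * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    size_t xoff = (size_t)n * C * H * W, yoff = (size_t)n * C * Ho * Wo;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int c = 0; c < C; ++c) {
          size_t best = 0;
          double bv = -1e300;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              size_t xi = xoff + ((size_t)(2 * w + dw) * H + 2 * h + dh) * C + c;
              if (xp[xi] > bv) { bv = xp[xi]; best = xi; }
            }
          size_t yi = yoff + ((size_t)w * Ho + h) * C + c;
          yp[yi] = bv;
          ip[yi] = (int)best;
        }
  }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dy, IntegerVector idx,
                             IntegerVector dims) {
  NumericVector dx((size_t)dims[0] * dims[1] * dims[2] * dims[3]);
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  const size_t M = dy.size();
  for (size_t i = 0; i < M; ++i) dxp[ip[i]] += dyp[i];
  dx.attr("dim") = dims;
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x, IntegerVector dims) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  NumericVector y((size_t)C * 4 * H * W * N);
  const double* xp = x.begin();
  double* yp = y.begin();
  const int Ho = 2 * H, Wo = 2 * W;
  for (int n = 0; n < N; ++n) {
    size_t xoff = (size_t)n * C * H * W, yoff = (size_t)n * C * Ho * Wo;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const double* src = xp + xoff + ((size_t)(w / 2) * H + h / 2) * C;
        double* dst = yp + yoff + ((size_t)w * Ho + h) * C;
        for (int c = 0; c < C; ++c) dst[c] = src[c];
      }
  }
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector dy, IntegerVector dims) {
  // dims are the *input* (pre-upsampling) dims
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  NumericVector dx((size_t)C * H * W * N);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  const int Ho = 2 * H, Wo = 2 * W;
  for (int n = 0; n < N; ++n) {
    size_t xoff = (size_t)n * C * H * W, yoff = (size_t)n * C * Ho * Wo;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const double* src = dyp + yoff + ((size_t)w * Ho + h) * C;
        double* dst = dxp + xoff + ((size_t)(w / 2) * H + h / 2) * C;
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
  }
  dx.attr("dim") = dims;
  return dx;
}

// elementwise ELU and its backward (through the activation value), kept in
// C++ to avoid allocating ifelse temporaries on multi-megabyte maps
// [[Rcpp::export]]
NumericVector cpp_elu(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  const size_t M = x.size();
  for (size_t i = 0; i < M; ++i)
    yp[i] = xp[i] > 0 ? xp[i] : std::expm1(xp[i]);
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_elu_bw(NumericVector a, NumericVector da) {
  NumericVector g(a.size());
  const double* ap = a.begin();
  const double* dp = da.begin();
  double* gp = g.begin();
  const size_t M = a.size();
  for (size_t i = 0; i < M; ++i)
    gp[i] = dp[i] * (ap[i] > 0 ? 1.0 : ap[i] + 1.0);
  g.attr("dim") = a.attr("dim");
  return g;
}
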
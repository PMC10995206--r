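// Zero-normalized cross-correlation of a frame against a template, and
// bilinear sub-pixel stamping of a template onto a frame (the simulator's
// rendering primitive). Frames and templates are plain R matrices.
#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Same-size ZNCC map; positions where the template does not fully fit are
// filled with `fill` (border policy).
// [[Rcpp::export]]
NumericMatrix cpp_ncc_map(NumericMatrix frame, NumericMatrix tmpl,
                          double fill) {
  const int H = frame.nrow(), W = frame.ncol();
  const int th = tmpl.nrow(), tw = tmpl.ncol();
  const int rh = th / 2, rw = tw / 2;
  const int npx = th * tw;

  double tmean = 0.0;
  for (int j = 0; j < tw; ++j)
    for (int i = 0; i < th; ++i) tmean += tmpl(i, j);
  tmean /= npx;
  std::vector<double> tz(npx);
  double tnorm = 0.0;
  for (int j = 0; j < tw; ++j)
    for (int i = 0; i < th; ++i) {
      double v = tmpl(i, j) - tmean;
      tz[j * th + i] = v;
      tnorm += v * v;
    }
  tnorm = std::sqrt(tnorm);

  NumericMatrix out(H, W);
  std::fill(out.begin(), out.end(), fill);
  if (tnorm <= 0) return out;

  for (int c = rw; c < W - (tw - 1 - rw); ++c) {
    for (int r = rh; r < H - (th - 1 - rh); ++r) {
      double s = 0.0, ss = 0.0, cross = 0.0;
      for (int j = 0; j < tw; ++j) {
        int fc = c - rw + j;
        for (int i = 0; i < th; ++i) {
          double v = frame(r - rh + i, fc);
          s += v;
          ss += v * v;
          cross += v * tz[j * th + i];
        }
      }
      double fvar = ss - s * s / npx;
      out(r, c) = fvar > 1e-300 ? cross / (std::sqrt(fvar) * tnorm) : 0.0;
    }
  }
  return out;
}

// Adds amp * tmpl shifted to continuous position (r, c) (0-based pixel-centre
// coordinates of the template's peak reference point) into frame, by bilinear
// interpolation of the fractional shift. Modifies frame in place.
// [[Rcpp::export]]
void cpp_stamp(NumericMatrix frame, NumericMatrix tmpl,
               double r, double c, double pr, double pc, double amp) {
  const int H = frame.nrow(), W = frame.ncol();
  const int th = tmpl.nrow(), tw = tmpl.ncol();
  // integer anchor and fractional part: template pixel (pr, pc) lands at (r, c)
  const double r0 = r - pr, c0 = c - pc;
  const int ri = (int)std::floor(r0), ci = (int)std::floor(c0);
  const double fr = r0 - ri, fc = c0 - ci;
  const double w00 = (1 - fr) * (1 - fc), w10 = fr * (1 - fc);
  const double w01 = (1 - fr) * fc, w11 = fr * fc;

  for (int j = 0; j <= tw; ++j) {
    int col = ci + j;
    if (col < 0 || col >= W) continue;
    for (int i = 0; i <= th; ++i) {
      int row = ri + i;
      if (row < 0 || row >= H) continue;
      double v = 0.0;
      if (i < th && j < tw) v += w00 * tmpl(i, j);
      if (i > 0 && j < tw) v += w10 * tmpl(i - 1, j);
      if (i < th && j > 0) v += w01 * tmpl(i, j - 1);
      if (i > 0 && j > 0) v += w11 * tmpl(i - 1, j - 1);
      frame(row, col) += amp * v;
    }
  }
}
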
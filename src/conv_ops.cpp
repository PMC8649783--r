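// Hot path of the CNN engine: valid-padding convolution as im2col + GEMM,
// with the matching scatter-add for the input gradient. Activations are
// laid out (height, width, batch, channel) so the GEMM output of one conv
// stage is directly the next stage's input. R vectors are wrapped, not
// copied, on both sides of the interface.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat wrap_mat(NumericMatrix m) {
  return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}

// Fill the im2col matrix: rows ordered (oh fastest, ow, batch), columns
// ordered (ki fastest, kj, channel).
static void im2col_fill(const double* x, int H, int W, int B, int C,
                        int kh, int kw, double* out) {
  const int oh = H - kh + 1, ow = W - kw + 1;
  const size_t planeHW = (size_t)H * W;
  double* dst = out;
  for (int c = 0; c < C; ++c) {
    const size_t coff = (size_t)c * planeHW * B;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        for (int b = 0; b < B; ++b) {
          const double* src = x + coff + (size_t)b * planeHW +
                              (size_t)kj * H + ki;
          for (int j = 0; j < ow; ++j) {
            const double* s = src + (size_t)j * H;
            for (int i = 0; i < oh; ++i) *dst++ = s[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List conv_fwd_cpp(NumericVector x, int H, int W, int B, int C,
                  int kh, int kw, NumericMatrix Wm, NumericVector b,
                  bool keep_cols) {
  const int oh = H - kh + 1, ow = W - kw + 1;
  const R_xlen_t P = (R_xlen_t)oh * ow;
  const int K = kh * kw * C, F = Wm.ncol();
  NumericMatrix Xcol_r(P * B, K);
  im2col_fill(x.begin(), H, W, B, C, kh, kw, Xcol_r.begin());
  arma::mat Xcol = wrap_mat(Xcol_r);
  NumericMatrix Y_r(P * B, F);
  arma::mat Y = wrap_mat(Y_r);
  Y = Xcol * wrap_mat(Wm);
  // bias + ReLU, fused
  const double* bp = b.begin();
  for (int f = 0; f < F; ++f) {
    double* col = Y.colptr(f);
    const double bf = bp[f];
    const R_xlen_t n = P * B;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double v = col[i] + bf;
      col[i] = v > 0.0 ? v : 0.0;
    }
  }
  if (keep_cols)
    return List::create(_["Y"] = Y_r, _["Xcol"] = Xcol_r);
  return List::create(_["Y"] = Y_r);
}

// dYin is the gradient at the (post-ReLU) conv output, rows (oh, ow,
// batch), cols = filters; Ypost masks the dead units.
// [[Rcpp::export]]
List conv_bwd_cpp(NumericMatrix Ypost, NumericMatrix dYin,
                  NumericMatrix Xcol, NumericMatrix Wm,
                  int H, int W, int B, int C, int kh, int kw,
                  bool need_dx) {
  const int oh = H - kh + 1, ow = W - kw + 1;
  const R_xlen_t P = (R_xlen_t)oh * ow;
  const int K = kh * kw * C, F = Wm.ncol();
  NumericMatrix dY_r(dYin.nrow(), dYin.ncol());
  {
    const double* y = Ypost.begin();
    const double* s = dYin.begin();
    double* d = dY_r.begin();
    const R_xlen_t n = dYin.size();
    for (R_xlen_t i = 0; i < n; ++i) d[i] = y[i] > 0.0 ? s[i] : 0.0;
  }
  arma::mat dY = wrap_mat(dY_r);
  NumericMatrix dW_r(K, F);
  arma::mat dW = wrap_mat(dW_r);
  dW = wrap_mat(Xcol).t() * dY;
  NumericVector db_r(F);
  for (int f = 0; f < F; ++f) {
    const double* col = dY.colptr(f);
    double s = 0;
    for (R_xlen_t i = 0; i < (R_xlen_t)P * B; ++i) s += col[i];
    db_r[f] = s;
  }
  if (!need_dx)
    return List::create(_["dW"] = dW_r, _["db"] = db_r);
  NumericMatrix dXcol_r(P * B, K);
  arma::mat dXcol = wrap_mat(dXcol_r);
  dXcol = dY * wrap_mat(Wm).t();
  NumericVector dx_r((R_xlen_t)H * W * B * C);
  double* dx = dx_r.begin();
  const size_t planeHW = (size_t)H * W;
  const double* src = dXcol_r.begin();
  for (int c = 0; c < C; ++c) {
    const size_t coff = (size_t)c * planeHW * B;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        for (int b = 0; b < B; ++b) {
          double* dst = dx + coff + (size_t)b * planeHW +
                        (size_t)kj * H + ki;
          for (int j = 0; j < ow; ++j) {
            double* d = dst + (size_t)j * H;
            for (int i = 0; i < oh; ++i) d[i] += *src++;
          }
        }
      }
    }
  }
  return List::create(_["dW"] = dW_r, _["db"] = db_r, _["dx"] = dx_r);
}

// Max pooling over (ph x pw) blocks with matching stride on a
// (H, W, B, C) tensor; returns the pooled tensor and the linear indices
// (1-based, into the input) of each maximum for the backward pass.
// [[Rcpp::export]]
List pool_fwd_cpp(NumericVector x, int H, int W, int B, int C,
                  int ph, int pw, bool keep_argmax) {
  const int oh = H / ph, ow = W / pw;
  const R_xlen_t n_out = (R_xlen_t)oh * ow * B * C;
  NumericVector out(n_out);
  IntegerVector arg(keep_argmax ? n_out : 0);
  const size_t planeHW = (size_t)H * W;
  const double* xp = x.begin();
  double* op = out.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const size_t base = ((size_t)c * B + b) * planeHW;
      for (int j = 0; j < ow; ++j) {
        for (int i = 0; i < oh; ++i, ++o) {
          size_t best = base + (size_t)(j * pw) * H + (size_t)i * ph;
          double bv = xp[best];
          for (int dj = 0; dj < pw; ++dj) {
            const size_t coloff = base + (size_t)(j * pw + dj) * H;
            for (int di = 0; di < ph; ++di) {
              const size_t at = coloff + (size_t)i * ph + di;
              if (xp[at] > bv) { bv = xp[at]; best = at; }
            }
          }
          op[o] = bv;
          if (keep_argmax) arg[o] = (int)(best + 1);
        }
      }
    }
  }
  if (keep_argmax)
    return List::create(_["out"] = out, _["argmax"] = arg);
  return List::create(_["out"] = out);
}
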
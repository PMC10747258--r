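// Low-level kernels for the 1-D convolutional variational autoencoder.
// Activations are column-major R matrices of shape (batch, channels*length)
// with channel-fastest column layout; these routines do the index-heavy
// gather/scatter and per-channel work, leaving matrix products to BLAS in R.

#include <Rcpp.h>
#include <cmath>
#include <cstring>

using namespace Rcpp;

// gather: x (B x C*L, unpadded) -> (B*Lout x C*K) using 1-based column
// indices into the *unpadded* input; index 0 marks a padding tap (zeros).
// idx (Lout x C*K): result((b,t), j) = idx(t,j) ? x(b, idx(t, j)) : 0
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, const IntegerMatrix& idx) {
  const int b = x.nrow(), lout = idx.nrow(), ck = idx.ncol();
  NumericMatrix out(Rcpp::no_init(b * lout, ck));
  const double* xptr = x.begin();
  double* optr = out.begin();
  for (int j = 0; j < ck; ++j) {
    double* ocol = optr + (R_xlen_t)j * b * lout;
    for (int t = 0; t < lout; ++t) {
      const int col = idx(t, j);
      if (col > 0) {
        std::memcpy(ocol + (R_xlen_t)t * b,
                    xptr + (R_xlen_t)(col - 1) * b, sizeof(double) * b);
      } else {
        std::memset(ocol + (R_xlen_t)t * b, 0, sizeof(double) * b);
      }
    }
  }
  return out;
}

// scatter-add: m (B*Lout x C*K) -> x (B x ncol_out), adjoint of cpp_im2col;
// padding taps (index 0) are dropped
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& m, const IntegerMatrix& idx,
                         int b, int ncol_out) {
  const int lout = idx.nrow(), ck = idx.ncol();
  NumericMatrix x(b, ncol_out);
  const double* mptr = m.begin();
  double* xptr = x.begin();
  for (int j = 0; j < ck; ++j) {
    const double* mcol = mptr + (R_xlen_t)j * b * lout;
    for (int t = 0; t < lout; ++t) {
      const int col = idx(t, j);
      if (col == 0) continue;
      double* dst = xptr + (R_xlen_t)(col - 1) * b;
      const double* src = mcol + (R_xlen_t)t * b;
      for (int i = 0; i < b; ++i) dst[i] += src[i];
    }
  }
  return x;
}

// (B x C*L) channel-fastest -> (B*L x C) row blocks
// [[Rcpp::export]]
NumericMatrix cpp_to_rows(const NumericMatrix& x, int c) {
  const int b = x.nrow();
  const int l = x.ncol() / c;
  NumericMatrix out(b * l, c);
  for (int ch = 0; ch < c; ++ch) {
    double* ocol = out.begin() + (R_xlen_t)ch * b * l;
    for (int p = 0; p < l; ++p) {
      const double* src = x.begin() + (R_xlen_t)(ch + p * c) * b;
      std::memcpy(ocol + (R_xlen_t)p * b, src, sizeof(double) * b);
    }
  }
  return out;
}

// inverse of cpp_to_rows
// [[Rcpp::export]]
NumericMatrix cpp_to_chan(const NumericMatrix& y, int c, int b) {
  const int l = y.nrow() / b;
  NumericMatrix out(b, c * l);
  for (int ch = 0; ch < c; ++ch) {
    const double* ycol = y.begin() + (R_xlen_t)ch * b * l;
    for (int p = 0; p < l; ++p) {
      double* dst = out.begin() + (R_xlen_t)(ch + p * c) * b;
      std::memcpy(dst, ycol + (R_xlen_t)p * b, sizeof(double) * b);
    }
  }
  return out;
}

// per-channel mean and (biased) variance over batch and positions
// [[Rcpp::export]]
List cpp_bn_stats(const NumericMatrix& x, int c) {
  const int b = x.nrow(), ncol = x.ncol();
  const int l = ncol / c;
  NumericVector mu(c), var(c);
  for (int j = 0; j < ncol; ++j) {
    const int ch = j % c;
    const double* col = x.begin() + (R_xlen_t)j * b;
    double s = 0, s2 = 0;
    for (int i = 0; i < b; ++i) { s += col[i]; s2 += col[i] * col[i]; }
    mu[ch] += s; var[ch] += s2;
  }
  const double n = (double)b * l;
  for (int ch = 0; ch < c; ++ch) {
    mu[ch] /= n;
    var[ch] = var[ch] / n - mu[ch] * mu[ch];
    if (var[ch] < 0) var[ch] = 0;
  }
  return List::create(_["mu"] = mu, _["var"] = var);
}

// normalize and scale/shift: returns xhat and y
// [[Rcpp::export]]
List cpp_bn_apply(const NumericMatrix& x, const NumericVector& mu,
                  const NumericVector& invstd, const NumericVector& gamma,
                  const NumericVector& beta, int c) {
  const int b = x.nrow(), ncol = x.ncol();
  NumericMatrix xhat(b, ncol), y(b, ncol);
  for (int j = 0; j < ncol; ++j) {
    const int ch = j % c;
    const double m = mu[ch], is = invstd[ch], g = gamma[ch], bt = beta[ch];
    const double* col = x.begin() + (R_xlen_t)j * b;
    double* xh = xhat.begin() + (R_xlen_t)j * b;
    double* yy = y.begin() + (R_xlen_t)j * b;
    for (int i = 0; i < b; ++i) {
      const double v = (col[i] - m) * is;
      xh[i] = v;
      yy[i] = g * v + bt;
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// batch-norm backward: returns dx, dgamma, dbeta
// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& dy, const NumericMatrix& xhat,
                const NumericVector& invstd, const NumericVector& gamma,
                int c) {
  const int b = dy.nrow(), ncol = dy.ncol();
  const int l = ncol / c;
  const double n = (double)b * l;
  NumericVector dgamma(c), dbeta(c), s1(c), s2(c);
  for (int j = 0; j < ncol; ++j) {
    const int ch = j % c;
    const double* d = dy.begin() + (R_xlen_t)j * b;
    const double* xh = xhat.begin() + (R_xlen_t)j * b;
    double a = 0, bb = 0;
    for (int i = 0; i < b; ++i) { a += d[i] * xh[i]; bb += d[i]; }
    dgamma[ch] += a; dbeta[ch] += bb;
  }
  for (int ch = 0; ch < c; ++ch) {
    s1[ch] = dbeta[ch] * gamma[ch];          // sum of dxhat
    s2[ch] = dgamma[ch] * gamma[ch];         // sum of dxhat * xhat
  }
  NumericMatrix dx(b, ncol);
  for (int j = 0; j < ncol; ++j) {
    const int ch = j % c;
    const double g = gamma[ch], is = invstd[ch];
    const double a1 = s1[ch] / n, a2 = s2[ch] / n;
    const double* d = dy.begin() + (R_xlen_t)j * b;
    const double* xh = xhat.begin() + (R_xlen_t)j * b;
    double* o = dx.begin() + (R_xlen_t)j * b;
    for (int i = 0; i < b; ++i) {
      o[i] = is * (d[i] * g - a1 - xh[i] * a2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ELU activation and its gradient (multiplied into dy in place of a copy)
// [[Rcpp::export]]
NumericMatrix cpp_elu(const NumericMatrix& x) {
  NumericMatrix y = clone(x);
  double* p = y.begin();
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = std::exp(p[i]) - 1;
  return y;
}

// returns dy * elu'(pre), where act = elu(pre)
// [[Rcpp::export]]
NumericMatrix cpp_elu_grad_mul(const NumericMatrix& dy,
                               const NumericMatrix& pre,
                               const NumericMatrix& act) {
  NumericMatrix out = clone(dy);
  double* o = out.begin();
  const double* p = pre.begin();
  const double* a = act.begin();
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] <= 0) o[i] *= a[i] + 1;
  return out;
}

// add per-channel bias in channel-fastest layout
// [[Rcpp::export]]
NumericMatrix cpp_add_channel_bias(const NumericMatrix& x,
                                   const NumericVector& bias, int c) {
  NumericMatrix y = clone(x);
  const int b = y.nrow(), ncol = y.ncol();
  for (int j = 0; j < ncol; ++j) {
    const double bv = bias[j % c];
    double* col = y.begin() + (R_xlen_t)j * b;
    for (int i = 0; i < b; ++i) col[i] += bv;
  }
  return y;
}

// per-channel sums in channel-fastest layout
// [[Rcpp::export]]
NumericVector cpp_channel_sums(const NumericMatrix& x, int c) {
  const int b = x.nrow(), ncol = x.ncol();
  NumericVector out(c);
  for (int j = 0; j < ncol; ++j) {
    const double* col = x.begin() + (R_xlen_t)j * b;
    double s = 0;
    for (int i = 0; i < b; ++i) s += col[i];
    out[j % c] += s;
  }
  return out;
}
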
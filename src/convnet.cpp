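// Convolution engine for the compact U-net. Feature maps are
// (B*H*W) x C matrices (column-major pixel order per image). 3x3
// convolutions run as im2col + GEMM in single precision, which is ample
// for SGD-style training; batch-norm statistics and reductions stay in
// double. The backward pass rebuilds im2col instead of caching it, keeping
// the training memory footprint at a few activation maps.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::fmat to_fmat(const NumericMatrix& X) {
  arma::fmat F(X.nrow(), X.ncol());
  const double* src = REAL(X);
  float* dst = F.memptr();
  const R_xlen_t n = (R_xlen_t)X.nrow() * X.ncol();
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return F;
}

static NumericMatrix to_dmat(const arma::fmat& F) {
  NumericMatrix X(F.n_rows, F.n_cols);
  double* dst = REAL(X);
  const float* src = F.memptr();
  const R_xlen_t n = (R_xlen_t)F.n_rows * F.n_cols;
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = (double)src[i];
  return X;
}

// 3x3 im2col with zero padding; offset block o = (dc+1)*3 + (dr+1)
// occupies columns [o*C, (o+1)*C).
static arma::fmat im2col3f(const arma::fmat& X, int B, int H, int W) {
  const int C = X.n_cols;
  const int npix = H * W;
  const arma::uword n = (arma::uword)B * npix;
  arma::fmat out(n, 9 * C);
  for (int dc = -1; dc <= 1; ++dc)
    for (int dr = -1; dr <= 1; ++dr) {
      const int o = (dc + 1) * 3 + (dr + 1);
      for (int ch = 0; ch < C; ++ch) {
        const float* src = X.colptr(ch);
        float* dst = out.colptr(o * C + ch);
        for (int b = 0; b < B; ++b) {
          const arma::uword ib = (arma::uword)b * npix;
          for (int c = 0; c < W; ++c) {
            const int cs = c + dc;
            float* drow = dst + ib + (arma::uword)c * H;
            if (cs < 0 || cs >= W) {
              std::fill(drow, drow + H, 0.0f);
              continue;
            }
            const float* srow = src + ib + (arma::uword)cs * H;
            if (dr == 0) {
              std::copy(srow, srow + H, drow);
            } else {
              for (int r = 0; r < H; ++r) {
                const int rs = r + dr;
                drow[r] = (rs < 0 || rs >= H) ? 0.0f : srow[rs];
              }
            }
          }
        }
      }
    }
  return out;
}

static arma::fmat col2im3f(const arma::fmat& G, int B, int H, int W, int C) {
  const int npix = H * W;
  arma::fmat out((arma::uword)B * npix, C, arma::fill::zeros);
  for (int dc = -1; dc <= 1; ++dc)
    for (int dr = -1; dr <= 1; ++dr) {
      const int o = (dc + 1) * 3 + (dr + 1);
      for (int ch = 0; ch < C; ++ch) {
        const float* src = G.colptr(o * C + ch);
        float* dst = out.colptr(ch);
        for (int b = 0; b < B; ++b) {
          const arma::uword ib = (arma::uword)b * npix;
          for (int c = 0; c < W; ++c) {
            const int cs = c + dc;
            if (cs < 0 || cs >= W) continue;
            const float* srow = src + ib + (arma::uword)c * H;
            float* drow = dst + ib + (arma::uword)cs * H;
            for (int r = 0; r < H; ++r) {
              const int rs = r + dr;
              if (rs >= 0 && rs < H) drow[rs] += srow[r];
            }
          }
        }
      }
    }
  return out;
}

// [[Rcpp::export(name = ".conv3_fwd")]]
NumericMatrix conv3_fwd(const NumericMatrix& X, const NumericMatrix& W,
                        int B, int H, int Wd) {
  arma::fmat Xf = to_fmat(X);
  arma::fmat Wf = to_fmat(W);
  arma::fmat Y = im2col3f(Xf, B, H, Wd) * Wf;
  return to_dmat(Y);
}

// [[Rcpp::export(name = ".conv3_bwd")]]
List conv3_bwd(const NumericMatrix& X, const NumericMatrix& W,
               const NumericMatrix& dY, int B, int H, int Wd,
               bool need_dx) {
  arma::fmat Xf = to_fmat(X);
  arma::fmat Wf = to_fmat(W);
  arma::fmat dYf = to_fmat(dY);
  arma::fmat Cols = im2col3f(Xf, B, H, Wd);
  arma::fmat dW = Cols.t() * dYf;
  List out = List::create(Named("dW") = to_dmat(dW));
  if (need_dx) {
    arma::fmat dCols = dYf * Wf.t();
    out["dX"] = to_dmat(col2im3f(dCols, B, H, Wd, Xf.n_cols));
  }
  return out;
}

// Fused batch-norm + ReLU forward over the batch (rows). Returns the
// activated output, the normalized input, 1/sd, and the batch mean/var
// for the running statistics.
// [[Rcpp::export(name = ".bnrelu_fwd")]]
List bnrelu_fwd(const NumericMatrix& X, const NumericVector& gamma,
                const NumericVector& beta, double eps) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix Y(n, C), xhat(n, C);
  NumericVector mu(C), var(C), inv_sd(C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, 0) + (R_xlen_t)c * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += x[i];
    const double m = s / n;
    double v = 0.0;
    for (int i = 0; i < n; ++i) { const double d = x[i] - m; v += d * d; }
    v /= n;
    const double is = 1.0 / std::sqrt(v + eps);
    mu[c] = m; var[c] = v; inv_sd[c] = is;
    const double g = gamma[c], b = beta[c];
    double* xh = &xhat(0, 0) + (R_xlen_t)c * n;
    double* y = &Y(0, 0) + (R_xlen_t)c * n;
    for (int i = 0; i < n; ++i) {
      const double z = (x[i] - m) * is;
      xh[i] = z;
      const double a = g * z + b;
      y[i] = a > 0.0 ? a : 0.0;
    }
  }
  return List::create(Named("Y") = Y, Named("xhat") = xhat,
                      Named("inv_sd") = inv_sd, Named("mu") = mu,
                      Named("var") = var);
}

// Backward of the fused batch-norm + ReLU; Y is the forward output
// (its positivity is the ReLU mask).
// [[Rcpp::export(name = ".bnrelu_bwd")]]
List bnrelu_bwd(const NumericMatrix& dY, const NumericMatrix& Y,
                const NumericMatrix& xhat, const NumericVector& inv_sd,
                const NumericVector& gamma) {
  const int n = dY.nrow(), C = dY.ncol();
  NumericMatrix dX(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dy = &dY(0, 0) + (R_xlen_t)c * n;
    const double* y = &Y(0, 0) + (R_xlen_t)c * n;
    const double* xh = &xhat(0, 0) + (R_xlen_t)c * n;
    double sg = 0.0, sb = 0.0, sxh = 0.0;
    for (int i = 0; i < n; ++i) {
      if (y[i] > 0.0) {
        sb += dy[i];
        sg += dy[i] * xh[i];
      }
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double g = gamma[c], is = inv_sd[c];
    const double m1 = sb / n;     // mean of masked dY
    const double m2 = sg / n;     // mean of masked dY * xhat
    double* dx = &dX(0, 0) + (R_xlen_t)c * n;
    for (int i = 0; i < n; ++i) {
      const double d = y[i] > 0.0 ? dy[i] : 0.0;
      dx[i] = g * is * (d - m1 - xh[i] * m2);
    }
    (void)sxh;
  }
  return List::create(Named("dX") = dX, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
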
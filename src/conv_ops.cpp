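// Convolution kernels for the G-RRDB engine.
//
// Layout conventions (match R arrays, column-major):
//   feature map  : H x W x C array (H fastest)
//   conv weight  : R array dim c(k, k, Cin, Cout), flattened index
//                  i + k*j + k*k*c + k*k*Cin*o
//   depthwise w  : R array dim c(k, k, mult, C); output slice = c*mult + m
// All convolutions are cross-correlations with zero "same" padding and
// stride 1; the effective pad is dil*(k-1)/2 (odd k only).
//
// The dense convolutions have few output channels relative to input
// channels, so the classic im2col of the input (H*W x k*k*Cin) is memory
// bound. Instead the forward pass runs one GEMM of the unshifted input
// matrix (H*W x Cin, small enough to stay in cache) against the kernel-
// offset-stacked weights (Cin x k*k*Cout) and scatter-adds the k*k offset
// blocks into the output. The backward pass builds the offset-stacked
// gradient (H*W x k*k*Cout, cheap because Cout is small) and needs just two
// GEMMs. Arrays are aliased, never copied, across the R boundary.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::cube alias_cube(SEXP x, int H, int W, int C) {
  return arma::cube(REAL(x), H, W, C, false, true);
}

static NumericVector alloc_array(int H, int W, int C) {
  NumericVector out(Rcpp::no_init((R_xlen_t)H * W * C));
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// Stack weights by kernel offset: Wall(c, o + Cout*(i + k*j)) = w[i,j,c,o].
static arma::mat stack_weights(const double* w, int k, int Cin, int Cout) {
  arma::mat Wall(Cin, (arma::uword)k * k * Cout);
  const int kk = k * k;
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int t = 0; t < kk; ++t)
        Wall(c, (arma::uword)o + (arma::uword)Cout * t) =
          w[t + kk * c + (arma::uword)kk * Cin * o];
  return Wall;
}

// [[Rcpp::export]]
SEXP cpp_conv2d_fwd(SEXP xs, SEXP ws, const arma::vec& b, const int k,
                    const int dil) {
  const IntegerVector xd(Rf_getAttrib(xs, R_DimSymbol));
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int Cout = b.n_elem;
  const int kk = k * k, ctr = (k - 1) / 2;
  const arma::mat X(REAL(xs), (arma::uword)H * W, Cin, false, true);
  const arma::mat Wall = stack_weights(REAL(ws), k, Cin, Cout);
  const arma::mat Yall = X * Wall;            // (H*W) x (k*k*Cout)
  NumericVector out = alloc_array(H, W, Cout);
  arma::cube oc(REAL(out), H, W, Cout, false, true);
  for (int o = 0; o < Cout; ++o) oc.slice(o).fill(b(o));
  for (int j = 0; j < k; ++j) {
    const int dw = dil * (j - ctr);
    for (int i = 0; i < k; ++i) {
      const int dh = dil * (i - ctr);
      const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
      const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
      if (h1 <= h0 || w1 <= w0) continue;
      for (int o = 0; o < Cout; ++o) {
        const arma::uword col = (arma::uword)o + (arma::uword)Cout * (i + k * j);
        const arma::mat P(const_cast<double*>(Yall.colptr(col)), H, W, false,
                          true);
        oc.slice(o).submat(h0, w0, h1 - 1, w1 - 1) +=
          P.submat(h0 + dh, w0 + dw, h1 - 1 + dh, w1 - 1 + dw);
      }
    }
  }
  return out;
}

// Offset-stacked gradient: G(p, o + Cout*(i+k*j)) = dy(h - dh, w - dw, o),
// zero where out of range (p = h + H*w).
static void stack_grad(const arma::cube& dy, int k, int dil, arma::mat& G) {
  const int H = dy.n_rows, W = dy.n_cols, Cout = dy.n_slices;
  const int ctr = (k - 1) / 2;
  G.zeros((arma::uword)H * W, (arma::uword)k * k * Cout);
  for (int j = 0; j < k; ++j) {
    const int dw = dil * (j - ctr);
    for (int i = 0; i < k; ++i) {
      const int dh = dil * (i - ctr);
      const int h0 = std::max(0, dh), h1 = std::min(H, H + dh);
      const int w0 = std::max(0, dw), w1 = std::min(W, W + dw);
      if (h1 <= h0 || w1 <= w0) continue;
      for (int o = 0; o < Cout; ++o) {
        const arma::uword col = (arma::uword)o + (arma::uword)Cout * (i + k * j);
        arma::mat Gp(G.colptr(col), H, W, false, true);
        Gp.submat(h0, w0, h1 - 1, w1 - 1) =
          dy.slice(o).submat(h0 - dh, w0 - dw, h1 - 1 - dh, w1 - 1 - dw);
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(SEXP xs, SEXP ws, SEXP dys, const int k, const int dil) {
  const IntegerVector xd(Rf_getAttrib(xs, R_DimSymbol));
  const IntegerVector yd(Rf_getAttrib(dys, R_DimSymbol));
  const int H = xd[0], W = xd[1], Cin = xd[2], Cout = yd[2];
  const int kk = k * k;
  const arma::mat X(REAL(xs), (arma::uword)H * W, Cin, false, true);
  const arma::cube dyc = alias_cube(dys, H, W, Cout);
  const arma::mat Wall = stack_weights(REAL(ws), k, Cin, Cout);
  arma::mat G;
  stack_grad(dyc, k, dil, G);                 // (H*W) x (k*k*Cout)
  // dX = G * Wall', back in (H*W) x Cin layout
  NumericVector dx = alloc_array(H, W, Cin);
  arma::mat dxm(REAL(dx), (arma::uword)H * W, Cin, false, true);
  dxm = G * Wall.t();
  // dW(c, q) then remapped to the R weight layout
  const arma::mat dWall = X.t() * G;          // Cin x (k*k*Cout)
  NumericVector dw(Rcpp::no_init((R_xlen_t)kk * Cin * Cout));
  dw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  double* dwp = REAL(dw);
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int t = 0; t < kk; ++t)
        dwp[t + kk * c + (arma::uword)kk * Cin * o] =
          dWall(c, (arma::uword)o + (arma::uword)Cout * t);
  arma::vec db(Cout);
  for (int o = 0; o < Cout; ++o) db(o) = arma::accu(dyc.slice(o));
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Depthwise convolution with channel multiplier; direct per-channel loops
// (each 2-D slice is cache resident). Inner loops run down contiguous h.
// [[Rcpp::export]]
SEXP cpp_dwconv2d_fwd(SEXP xs, SEXP ws, const arma::vec& b, const int k,
                      const int dil, const int mult) {
  const IntegerVector xd(Rf_getAttrib(xs, R_DimSymbol));
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kk = k * k, ctr = (k - 1) / 2;
  const arma::cube x = alias_cube(xs, H, W, C);
  const double* wv = REAL(ws);
  NumericVector out = alloc_array(H, W, C * mult);
  arma::cube oc(REAL(out), H, W, (arma::uword)C * mult, false, true);
  for (int c = 0; c < C; ++c) {
    for (int m = 0; m < mult; ++m) {
      const int o = c * mult + m;
      arma::mat& dst = oc.slice(o);
      dst.fill(b(o));
      const double* wk = wv + (arma::uword)kk * (m + (arma::uword)mult * c);
      const arma::mat& src = x.slice(c);
      for (int j = 0; j < k; ++j) {
        const int dw = dil * (j - ctr);
        for (int i = 0; i < k; ++i) {
          const int dh = dil * (i - ctr);
          const double coef = wk[i + k * j];
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
          if (h1 <= h0 || w1 <= w0) continue;
          for (int w = w0; w < w1; ++w) {
            double* dp = dst.colptr(w) + h0;
            const double* sp = src.colptr(w + dw) + h0 + dh;
            const int n = h1 - h0;
            for (int t = 0; t < n; ++t) dp[t] += coef * sp[t];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv2d_bwd(SEXP xs, SEXP ws, SEXP dys, const int k, const int dil,
                      const int mult) {
  const IntegerVector xd(Rf_getAttrib(xs, R_DimSymbol));
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kk = k * k, ctr = (k - 1) / 2;
  const arma::cube x = alias_cube(xs, H, W, C);
  const arma::cube dy = alias_cube(dys, H, W, (arma::uword)C * mult);
  const double* wv = REAL(ws);
  NumericVector dx = alloc_array(H, W, C);
  arma::cube dxc(REAL(dx), H, W, C, false, true);
  dxc.zeros();
  NumericVector dw(Rcpp::no_init((R_xlen_t)kk * mult * C));
  dw.attr("dim") = IntegerVector::create(k, k, mult, C);
  double* dwp = REAL(dw);
  std::fill(dwp, dwp + (R_xlen_t)kk * mult * C, 0.0);
  arma::vec db((arma::uword)C * mult, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int m = 0; m < mult; ++m) {
      const int o = c * mult + m;
      const arma::mat& g = dy.slice(o);
      const arma::mat& src = x.slice(c);
      arma::mat& dxs = dxc.slice(c);
      db(o) = arma::accu(g);
      const double* wk = wv + (arma::uword)kk * (m + (arma::uword)mult * c);
      double* dwk = dwp + (arma::uword)kk * (m + (arma::uword)mult * c);
      for (int j = 0; j < k; ++j) {
        const int dw_ = dil * (j - ctr);
        for (int i = 0; i < k; ++i) {
          const int dh = dil * (i - ctr);
          const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const int w0 = std::max(0, -dw_), w1 = std::min(W, W - dw_);
          if (h1 <= h0 || w1 <= w0) continue;
          const double coef = wk[i + k * j];
          double acc = 0.0;
          for (int w = w0; w < w1; ++w) {
            const double* gp = g.colptr(w) + h0;
            const double* sp = src.colptr(w + dw_) + h0 + dh;
            double* dp = dxs.colptr(w + dw_) + h0 + dh;
            const int n = h1 - h0;
            for (int t = 0; t < n; ++t) {
              acc += gp[t] * sp[t];
              dp[t] += coef * gp[t];
            }
          }
          dwk[i + k * j] += acc;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
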
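// 3x3 same-padding 2D convolution on batched activation matrices.
//
// Activations are (H*W*N) x C matrices: rows iterate h fastest, then w,
// then sample n; columns are channels. The convolution is expressed as
// an im2col gather followed by one BLAS matrix product; the backward
// pass reuses the forward's im2col matrix for the weight gradient and a
// col2im scatter for the input gradient. Kernel-offset blocks of the
// weight matrix are ordered o = dw*3 + dh (o = 4 is the centre tap).
// All matrices are borrowed from / written into R memory without copies.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void im2col_fill(const mat& X, mat& Xcol, int H, int W, int N) {
  const int cin = X.n_cols;
  const int HW = H * W;
  for (int o = 0; o < 9; ++o) {
    const int dw = o / 3 - 1;
    const int dh = o % 3 - 1;
    for (int ci = 0; ci < cin; ++ci) {
      const double* src = X.colptr(ci);
      double* dst = Xcol.colptr(o * cin + ci);
      for (int n = 0; n < N; ++n) {
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw;
          double* drow = dst + (size_t)n * HW + (size_t)w * H;
          if (ws < 0 || ws >= W) {
            std::fill(drow, drow + H, 0.0);
            continue;
          }
          const double* srow = src + (size_t)n * HW + (size_t)ws * H;
          const int h0 = std::max(0, -dh);
          const int h1 = std::min(H, H - dh);
          for (int h = 0; h < h0; ++h) drow[h] = 0.0;
          for (int h = h1; h < H; ++h) drow[h] = 0.0;
          if (h1 > h0)
            std::memcpy(drow + h0, srow + h0 + dh,
                        (size_t)(h1 - h0) * sizeof(double));
        }
      }
    }
  }
}

static void col2im_add(const mat& dXcol, mat& dX, int H, int W, int N) {
  const int cin = dX.n_cols;
  const int HW = H * W;
  for (int o = 0; o < 9; ++o) {
    const int dw = o / 3 - 1;
    const int dh = o % 3 - 1;
    for (int ci = 0; ci < cin; ++ci) {
      const double* src = dXcol.colptr(o * cin + ci);
      double* dst = dX.colptr(ci);
      for (int n = 0; n < N; ++n) {
        for (int w = 0; w < W; ++w) {
          const int ws = w + dw;
          if (ws < 0 || ws >= W) continue;
          const double* srow = src + (size_t)n * HW + (size_t)w * H;
          double* drow = dst + (size_t)n * HW + (size_t)ws * H;
          const int h0 = std::max(0, -dh);
          const int h1 = std::min(H, H - dh);
          for (int h = h0; h < h1; ++h) drow[h + dh] += srow[h];
        }
      }
    }
  }
}

// forward pass; returns Y and the im2col matrix for reuse in backward
// [[Rcpp::export]]
Rcpp::List cpp_conv_fwd(Rcpp::NumericMatrix Xr, Rcpp::NumericMatrix Wr,
                        Rcpp::NumericVector br, int H, int W, int N) {
  const int rows = H * W * N;
  const int cin = Xr.ncol();
  const int cout = Wr.ncol();
  const mat X(Xr.begin(), rows, cin, false);
  const mat Wm(Wr.begin(), 9 * cin, cout, false);
  const vec b(br.begin(), cout, false);
  Rcpp::NumericMatrix Xcolr(Rf_allocMatrix(REALSXP, rows, 9 * cin));
  mat Xcol(Xcolr.begin(), rows, 9 * cin, false);
  im2col_fill(X, Xcol, H, W, N);
  Rcpp::NumericMatrix Yr(Rf_allocMatrix(REALSXP, rows, cout));
  mat Y(Yr.begin(), rows, cout, false);
  Y = Xcol * Wm;
  Y.each_row() += b.t();
  return Rcpp::List::create(Rcpp::Named("Y") = Yr,
                            Rcpp::Named("Xcol") = Xcolr);
}

// backward pass from the cached im2col matrix
// [[Rcpp::export]]
Rcpp::List cpp_conv_bwd(Rcpp::NumericMatrix Xcolr, Rcpp::NumericMatrix Wr,
                        Rcpp::NumericMatrix dYr, int H, int W, int N,
                        bool need_dx) {
  const int rows = H * W * N;
  const int cin9 = Xcolr.ncol();
  const int cin = cin9 / 9;
  const int cout = Wr.ncol();
  const mat Xcol(Xcolr.begin(), rows, cin9, false);
  const mat Wm(Wr.begin(), cin9, cout, false);
  const mat dY(dYr.begin(), rows, cout, false);
  Rcpp::NumericMatrix dWr(cin9, cout);
  mat dW(dWr.begin(), cin9, cout, false);
  dW = Xcol.t() * dY;
  Rcpp::NumericVector dbr(cout);
  vec db(dbr.begin(), cout, false);
  db = sum(dY, 0).t();
  Rcpp::NumericMatrix dXr(0, 0);
  if (need_dx) {
    mat dXcol = dY * Wm.t();
    dXr = Rcpp::NumericMatrix(rows, cin);
    mat dX(dXr.begin(), rows, cin, false);
    col2im_add(dXcol, dX, H, W, N);
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dXr,
                            Rcpp::Named("dW") = dWr,
                            Rcpp::Named("db") = dbr);
}

// fused batch-norm + ReLU forward (training mode uses batch statistics)
// [[Rcpp::export]]
Rcpp::List cpp_bnrelu_fwd(Rcpp::NumericMatrix Xr, Rcpp::NumericVector g,
                          Rcpp::NumericVector bt, Rcpp::NumericVector mu,
                          Rcpp::NumericVector invstd) {
  const int M = Xr.nrow(), C = Xr.ncol();
  const mat X(Xr.begin(), M, C, false);
  Rcpp::NumericMatrix Yr(Rf_allocMatrix(REALSXP, M, C));
  Rcpp::NumericMatrix Xhatr(Rf_allocMatrix(REALSXP, M, C));
  mat Y(Yr.begin(), M, C, false);
  mat Xhat(Xhatr.begin(), M, C, false);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], is = invstd[c], gc = g[c], bc = bt[c];
    const double* x = X.colptr(c);
    double* xh = Xhat.colptr(c);
    double* y = Y.colptr(c);
    for (int i = 0; i < M; ++i) {
      const double h = (x[i] - m) * is;
      xh[i] = h;
      const double v = h * gc + bc;
      y[i] = v > 0 ? v : 0.0;
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Yr,
                            Rcpp::Named("xhat") = Xhatr);
}
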
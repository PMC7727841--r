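// Batched 1-D convolution and max-pooling primitives for the catch/drop CNN.
// Layout: a batch is a cube T x C x N (time steps, channels, samples).
// Convolution weights are (k * C) x F with row index j * C + c for tap j and
// input channel c. The whole batch is gathered into one stacked im2col
// matrix ((N * T_out) x (k * C)) so forward and backward each reduce to a
// single GEMM; the forward pass hands the workspace back so the backward
// pass can reuse it.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void fill_im2col(const cube& x, int k, int stride, int T_out, mat& col) {
  const int T = x.n_rows, C = x.n_cols, N = x.n_slices;
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < C; ++c) {
      double* dst = col.colptr(j * C + c);
      for (int n = 0; n < N; ++n) {
        const double* src = x.slice_colptr(n, c) + j;
        double* d = dst + (size_t)n * T_out;
        for (int t = 0; t < T_out; ++t) d[t] = src[(size_t)t * stride];
      }
    }
  (void)T;
}

// [[Rcpp::export]]
Rcpp::List conv1d_forward(Rcpp::NumericVector xr, const arma::mat& W,
                          const arma::vec& b, int k, int stride) {
  Rcpp::IntegerVector dm = xr.attr("dim");
  if (dm.size() != 3) Rcpp::stop("input must be a 3-D array");
  const cube x(xr.begin(), dm[0], dm[1], dm[2], false);  // borrow, no copy
  const int T = x.n_rows, C = x.n_cols, N = x.n_slices;
  if ((int)W.n_rows != k * C)
    Rcpp::stop("weight rows (%d) != kernel * channels (%d)", (int)W.n_rows, k * C);
  if (T < k) Rcpp::stop("kernel longer than input");
  const int T_out = (T - k) / stride + 1;
  const int F = W.n_cols;
  // allocate the workspace as an R matrix so returning it is free
  Rcpp::NumericMatrix colr((R_xlen_t)N * T_out, (R_xlen_t)k * C);
  mat col(colr.begin(), (uword)N * T_out, (uword)k * C, false);
  fill_im2col(x, k, stride, T_out, col);
  mat res = col * W;
  res.each_row() += b.t();
  Rcpp::NumericVector outr((R_xlen_t)T_out * F * N);
  outr.attr("dim") = Rcpp::IntegerVector::create(T_out, F, N);
  cube out(outr.begin(), T_out, F, N, false);
  for (int n = 0; n < N; ++n)
    out.slice(n) = res.rows((uword)n * T_out, (uword)(n + 1) * T_out - 1);
  return Rcpp::List::create(Rcpp::Named("out") = outr,
                            Rcpp::Named("col") = colr);
}

// col: the im2col workspace returned by conv1d_forward for the same x.
// [[Rcpp::export]]
Rcpp::List conv1d_backward(const arma::mat& col, const arma::mat& W,
                           const arma::cube& gout, int k, int stride,
                           int T_in, bool need_dx) {
  const int T_out = gout.n_rows, F = gout.n_cols, N = gout.n_slices;
  const int C = W.n_rows / k;
  mat gstack((uword)N * T_out, F);
  for (int n = 0; n < N; ++n)
    gstack.rows((uword)n * T_out, (uword)(n + 1) * T_out - 1) = gout.slice(n);
  mat dW = col.t() * gstack;
  vec db = sum(gstack, 0).t();
  cube dx;
  if (need_dx) {
    dx.zeros(T_in, C, N);
    mat dcol = gstack * W.t();
    for (int j = 0; j < k; ++j)
      for (int c = 0; c < C; ++c) {
        const double* src = dcol.colptr(j * C + c);
        for (int n = 0; n < N; ++n) {
          double* dst = dx.slice_colptr(n, c) + j;
          const double* s = src + (size_t)n * T_out;
          for (int t = 0; t < T_out; ++t) dst[(size_t)t * stride] += s[t];
        }
      }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Non-overlapping max pooling over time; returns pooled values and the
// flat argmax indices (1-based within each T dimension) for the backward pass.
// [[Rcpp::export]]
Rcpp::List maxpool_forward(const arma::cube& x, int pool) {
  const int T = x.n_rows, C = x.n_cols, N = x.n_slices;
  const int T_out = T / pool;
  if (T_out < 1) Rcpp::stop("pool size larger than input");
  cube out(T_out, C, N);
  icube idx(T_out, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = x.slice_colptr(n, c);
      double* dst = out.slice_colptr(n, c);
      sword* ix = idx.slice_colptr(n, c);
      for (int t = 0; t < T_out; ++t) {
        int base = t * pool;
        double best = src[base];
        int bi = base;
        for (int j = 1; j < pool; ++j)
          if (src[base + j] > best) { best = src[base + j]; bi = base + j; }
        dst[t] = best;
        ix[t] = bi + 1;
      }
    }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool_backward(const arma::icube& idx, const arma::cube& gout,
                            int T_in) {
  const int T_out = gout.n_rows, C = gout.n_cols, N = gout.n_slices;
  cube dx(T_in, C, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* g = gout.slice_colptr(n, c);
      const sword* ix = idx.slice_colptr(n, c);
      double* d = dx.slice_colptr(n, c);
      for (int t = 0; t < T_out; ++t) d[ix[t] - 1] += g[t];
    }
  return dx;
}

// Standardize each channel with per-channel location/scale.
// [[Rcpp::export]]
Rcpp::NumericVector standardize_cube(Rcpp::NumericVector xr, const arma::vec& mu,
                                     const arma::vec& sdev) {
  Rcpp::IntegerVector dm = xr.attr("dim");
  if (dm.size() != 3) Rcpp::stop("input must be a 3-D array");
  const int T = dm[0], C = dm[1], N = dm[2];
  Rcpp::NumericVector outr((R_xlen_t)T * C * N);
  outr.attr("dim") = dm;
  const double* src = xr.begin();
  double* dst = outr.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double m = mu(c), s = sdev(c);
      const double* sp = src + ((size_t)n * C + c) * T;
      double* dp = dst + ((size_t)n * C + c) * T;
      for (int t = 0; t < T; ++t) dp[t] = (sp[t] - m) / s;
    }
  return outr;
}

// Gather sample slices idx (1-based) of a T x C x N array: one memcpy per
// (channel, sample) column.
// [[Rcpp::export]]
Rcpp::NumericVector subset_cube(Rcpp::NumericVector xr, Rcpp::IntegerVector idx) {
  Rcpp::IntegerVector dm = xr.attr("dim");
  if (dm.size() != 3) Rcpp::stop("input must be a 3-D array");
  const int T = dm[0], C = dm[1], N = dm[2];
  const int M = idx.size();
  Rcpp::NumericVector outr((R_xlen_t)T * C * M);
  outr.attr("dim") = Rcpp::IntegerVector::create(T, C, M);
  const double* src = xr.begin();
  double* dst = outr.begin();
  const size_t slice = (size_t)T * C;
  for (int m = 0; m < M; ++m) {
    int n = idx[m] - 1;
    if (n < 0 || n >= N) Rcpp::stop("index out of range");
    std::memcpy(dst + m * slice, src + (size_t)n * slice, slice * sizeof(double));
  }
  return outr;
}

// im2col workspace only (for caching block-1 columns across epochs)
// [[Rcpp::export]]
Rcpp::NumericMatrix im2col_only(Rcpp::NumericVector xr, int k, int stride) {
  Rcpp::IntegerVector dm = xr.attr("dim");
  if (dm.size() != 3) Rcpp::stop("input must be a 3-D array");
  const cube x(const_cast<double*>(xr.begin()), dm[0], dm[1], dm[2], false);
  const int T = x.n_rows, C = x.n_cols, N = x.n_slices;
  if (T < k) Rcpp::stop("kernel longer than input");
  const int T_out = (T - k) / stride + 1;
  Rcpp::NumericMatrix colr((R_xlen_t)N * T_out, (R_xlen_t)k * C);
  mat col(colr.begin(), (uword)N * T_out, (uword)k * C, false);
  fill_im2col(x, k, stride, T_out, col);
  return colr;
}

// convolution forward on a precomputed im2col workspace
// [[Rcpp::export]]
Rcpp::NumericVector conv1d_forward_col(Rcpp::NumericMatrix colr,
                                       const arma::mat& W, const arma::vec& b,
                                       int n_samples) {
  const int rows = colr.nrow();
  const int T_out = rows / n_samples;
  const mat col(colr.begin(), rows, colr.ncol(), false);
  mat res = col * W;
  res.each_row() += b.t();
  const int F = W.n_cols;
  Rcpp::NumericVector outr((R_xlen_t)T_out * F * n_samples);
  outr.attr("dim") = Rcpp::IntegerVector::create(T_out, F, n_samples);
  cube out(outr.begin(), T_out, F, n_samples, false);
  for (int n = 0; n < n_samples; ++n)
    out.slice(n) = res.rows((uword)n * T_out, (uword)(n + 1) * T_out - 1);
  return outr;
}
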
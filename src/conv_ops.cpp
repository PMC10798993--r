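#include <Rcpp.h>
#include <R_ext/BLAS.h>
using namespace Rcpp;

// Shift-convolution primitives. A 3x3 same-padded convolution on feature
// maps stored as (N x C) matrices (N = B*H*W, column-major pixels) is the
// sum over the nine offsets k of a per-offset linear map applied to the
// row-shifted input: Y[i,] += (X W_k)[i + delta_k,]. Row shifts are plain
// pointer offsets in the column-major buffer (leading dimension N), so the
// shifted products run as single BLAS calls over the overlap range, with a
// small correction loop for the boundary pixels whose neighbour falls
// outside their own image (listed 1-based in `invalid`).

// Y[i, c] += Z[i + delta, c] for in-range i, then undo the invalid rows.
// Y is modified in place (the caller owns it).
// [[Rcpp::export]]
void add_shifted(NumericMatrix Y, const NumericMatrix& Z, const int delta,
                 const IntegerVector& invalid) {
  const R_xlen_t N = Y.nrow();
  const R_xlen_t C = Y.ncol();
  const R_xlen_t lo = std::max((R_xlen_t)1, (R_xlen_t)1 - delta);
  const R_xlen_t hi = std::min(N, N - delta);
  const int ni = invalid.size();
  const int* iv = ni > 0 ? INTEGER(invalid) : (const int*)nullptr;
  for (R_xlen_t c = 0; c < C; ++c) {
    double* yc = &Y(0, c);
    const double* zc = &Z(0, c);
    for (R_xlen_t i = lo - 1; i < hi; ++i) yc[i] += zc[i + delta];
    for (int j = 0; j < ni; ++j) {
      R_xlen_t i = iv[j] - 1;
      if (i >= lo - 1 && i < hi) yc[i] -= zc[i + delta];
    }
  }
}

// dW_k = sum over valid i of X[i + delta, ] (x) dY[i, ]  --  computed as
// t(X + delta) %*% dY over the overlap via dgemm, then boundary-corrected.
// [[Rcpp::export]]
NumericMatrix crossprod_shifted(const NumericMatrix& X, const NumericMatrix& dY,
                                const int delta, const IntegerVector& invalid) {
  const int N = X.nrow();
  const int C = X.ncol();
  const int K = dY.ncol();
  NumericMatrix out(C, K);
  const int lo = std::max(1, 1 - delta);
  const int hi = std::min(N, N - delta);
  const int m = hi - lo + 1;
  if (m > 0) {
    const double one = 1.0, zero = 0.0;
    const double* a = X.begin() + (lo - 1 + delta); // rows lo+delta .. hi+delta
    const double* b = dY.begin() + (lo - 1);
    F77_CALL(dgemm)("T", "N", &C, &K, &m, &one, a, &N, b, &N, &zero,
                    out.begin(), &C FCONE FCONE);
  }
  const int ni = invalid.size();
  for (int j = 0; j < ni; ++j) {
    int i = invalid[j] - 1;
    if (i < lo - 1 || i >= hi) continue;
    const double* xr = X.begin() + (i + delta);
    const double* yr = dY.begin() + i;
    for (int k = 0; k < K; ++k) {
      double yv = yr[(R_xlen_t)k * N];
      if (yv == 0.0) continue;
      double* oc = &out(0, k);
      for (int c = 0; c < C; ++c) oc[c] -= xr[(R_xlen_t)c * N] * yv;
    }
  }
  return out;
}

// dX[i + delta, ] += dY[i, ] %*% t(Wk) for valid i, in place, via a
// pointer-offset dgemm with beta = 1 plus boundary corrections.
// [[Rcpp::export]]
void acc_shifted_product(NumericMatrix dX, const NumericMatrix& dY,
                         const NumericMatrix& Wk, const int delta,
                         const IntegerVector& invalid) {
  const int N = dX.nrow();
  const int C = dX.ncol();
  const int K = dY.ncol(); // == Wk.ncol(); Wk is (C x K)
  const int lo = std::max(1, 1 - delta);
  const int hi = std::min(N, N - delta);
  const int m = hi - lo + 1;
  if (m > 0) {
    const double one = 1.0;
    const double* a = dY.begin() + (lo - 1);
    double* cptr = dX.begin() + (lo - 1 + delta);
    F77_CALL(dgemm)("N", "T", &m, &C, &K, &one, a, &N, Wk.begin(), &C, &one,
                    cptr, &N FCONE FCONE);
  }
  const int ni = invalid.size();
  for (int j = 0; j < ni; ++j) {
    int i = invalid[j] - 1;
    if (i < lo - 1 || i >= hi) continue;
    const double* yr = dY.begin() + i;
    double* xr = dX.begin() + (i + delta);
    for (int k = 0; k < K; ++k) {
      double yv = yr[(R_xlen_t)k * N];
      if (yv == 0.0) continue;
      const double* wc = &Wk(0, k);
      for (int c = 0; c < C; ++c) xr[(R_xlen_t)c * N] -= wc[c] * yv;
    }
  }
}

// BatchNorm forward: xhat = (X - mu) * istd per column; Y = xhat * g + b.
// Returns Y and writes xhat into the supplied buffer.
// [[Rcpp::export]]
NumericMatrix bn_apply(const NumericMatrix& X, const NumericVector& mu,
                       const NumericVector& istd, const NumericVector& gamma,
                       const NumericVector& beta, NumericMatrix xhat) {
  const R_xlen_t N = X.nrow();
  const R_xlen_t C = X.ncol();
  NumericMatrix Y((int)N, (int)C);
  for (R_xlen_t c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    double* hc = &xhat(0, c);
    double* yc = &Y(0, c);
    const double m = mu[c], is = istd[c], g = gamma[c], b = beta[c];
    for (R_xlen_t i = 0; i < N; ++i) {
      double h = (xc[i] - m) * is;
      hc[i] = h;
      yc[i] = h * g + b;
    }
  }
  return Y;
}

// BatchNorm backward input gradient:
// dX = (dxhat - s1/N - xhat * s2/N) * istd with dxhat = dY * gamma.
// [[Rcpp::export]]
NumericMatrix bn_input_grad(const NumericMatrix& dY, const NumericMatrix& xhat,
                            const NumericVector& gamma, const NumericVector& istd,
                            const NumericVector& s1, const NumericVector& s2) {
  const R_xlen_t N = dY.nrow();
  const R_xlen_t C = dY.ncol();
  NumericMatrix out((int)N, (int)C);
  for (R_xlen_t c = 0; c < C; ++c) {
    const double* dc = &dY(0, c);
    const double* hc = &xhat(0, c);
    double* oc = &out(0, c);
    const double g = gamma[c], is = istd[c];
    const double a1 = s1[c] / (double)N, a2 = s2[c] / (double)N;
    for (R_xlen_t i = 0; i < N; ++i) {
      oc[i] = (dc[i] * g - a1 - hc[i] * a2) * is;
    }
  }
  return out;
}
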
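#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// trace(A B) for symmetric A, B = sum of the elementwise product,
// without allocating the product
// [[Rcpp::export(name = ".fvTraceProd")]]
double fvTraceProd(NumericMatrix A, NumericMatrix B) {
  R_xlen_t n = A.size();
  if (n != B.size()) stop("dimension mismatch");
  const double *a = A.begin(), *b = B.begin();
  double s = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) s += a[i] * b[i];
  return s;
}

// fill V (preallocated n x n) with sum_i sigma[i] * mats[i]
// + (sigma[q] + ridge) * I, in place
// [[Rcpp::export(name = ".fvBuildV")]]
void fvBuildV(NumericMatrix V, List mats, NumericVector sigma,
              double ridge) {
  int n = V.nrow();
  int q = mats.size();
  if (sigma.size() != q + 1) stop("sigma must have q + 1 entries");
  std::fill(V.begin(), V.end(), 0.0);
  for (int k = 0; k < q; ++k) {
    NumericMatrix A = mats[k];
    if (A.nrow() != n) stop("matrix dimension mismatch");
    const double *a = A.begin();
    double *v = V.begin();
    double s = sigma[k];
    R_xlen_t nn = (R_xlen_t)n * n;
    for (R_xlen_t i = 0; i < nn; ++i) v[i] += s * a[i];
  }
  double d = sigma[q] + ridge;
  for (int i = 0; i < n; ++i) V(i, i) += d;
}

// copy V into Vi, Cholesky-factor and invert in place (LAPACK
// dpotrf/dpotri); returns the log-determinant of V, or NA when V is
// not positive definite.  Vi ends as the full symmetric inverse.
// [[Rcpp::export(name = ".fvCholInv")]]
double fvCholInv(NumericMatrix V, NumericMatrix Vi) {
  int n = V.nrow();
  if (Vi.nrow() != n || Vi.ncol() != n) stop("Vi dimension mismatch");
  std::copy(V.begin(), V.end(), Vi.begin());
  int info = 0;
  F77_CALL(dpotrf)("U", &n, Vi.begin(), &n, &info FCONE);
  if (info != 0) return NA_REAL;
  double logdet = 0.0;
  for (int i = 0; i < n; ++i) logdet += 2.0 * std::log(Vi(i, i));
  F77_CALL(dpotri)("U", &n, Vi.begin(), &n, &info FCONE);
  if (info != 0) return NA_REAL;
  for (int j = 0; j < n; ++j)          // mirror upper to lower
    for (int i = j + 1; i < n; ++i)
      Vi(i, j) = Vi(j, i);
  return logdet;
}

// centre and scale columns of W in place: (w - 2p) / sqrt(2p(1-p)),
// NA -> 0 (mean imputation after centring)
// [[Rcpp::export(name = ".fvStandardiseGeno")]]
void fvStandardiseGeno(NumericMatrix W, NumericVector p) {
  int n = W.nrow(), m = W.ncol();
  if (p.size() != m) stop("p length mismatch");
  for (int j = 0; j < m; ++j) {
    double mu = 2.0 * p[j];
    double s = std::sqrt(2.0 * p[j] * (1.0 - p[j]));
    double *col = &W(0, j);
    for (int i = 0; i < n; ++i) {
      if (ISNAN(col[i])) col[i] = 0.0;
      else col[i] = (col[i] - mu) / s;
    }
  }
}

// Hardy-Weinberg founder genotypes + per-SNP Mendelian transmission
// (linkage-equilibrium fast path).  fa/mo are 1-based indices into the
// parents-first-sorted individuals, 0 for founders.
// [[Rcpp::export(name = ".fvSimGenoLE")]]
NumericMatrix fvSimGenoLE(int nSnps, NumericVector maf,
                          IntegerVector fa, IntegerVector mo) {
  int n = fa.size();
  for (int i = 0; i < n; ++i)
    if (fa[i] > i || mo[i] > i)
      stop("parents must precede children");
  NumericMatrix G(n, nSnps);
  // SNP-outer so each column is filled sequentially (column-major)
  for (int j = 0; j < nSnps; ++j) {
    double *col = &G(0, j);
    double m = maf[j];
    for (int i = 0; i < n; ++i) {
      if (fa[i] == 0) {
        col[i] = (unif_rand() < m) + (unif_rand() < m);
      } else {
        col[i] = (unif_rand() < col[fa[i] - 1] / 2.0) +
                 (unif_rand() < col[mo[i] - 1] / 2.0);
      }
    }
  }
  return G;
}
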
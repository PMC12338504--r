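// In-place dense LU via LAPACK. The BEM system matrix at desk scale can be
// a couple of GB; factoring in place keeps peak memory at one copy.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Factor A in place (A becomes L\U); returns the pivot vector.
// [[Rcpp::export]]
IntegerVector cpp_lu_factor(NumericMatrix A) {
  int n = A.nrow();
  if (A.ncol() != n) stop("matrix must be square");
  IntegerVector ipiv(n);
  int info = 0;
  F77_CALL(dgetrf)(&n, &n, A.begin(), &n, ipiv.begin(), &info);
  if (info < 0) stop("dgetrf: illegal argument %d", -info);
  if (info > 0) stop("dgetrf: singular at pivot %d", info);
  return ipiv;
}

// Solve A X = B given the in-place factors; B is not modified.
// [[Rcpp::export]]
NumericMatrix cpp_lu_solve(NumericMatrix LU, IntegerVector ipiv,
                           NumericMatrix B) {
  int n = LU.nrow(), nrhs = B.ncol();
  if (B.nrow() != n) stop("dimension mismatch");
  NumericMatrix X = clone(B);
  int info = 0;
  F77_CALL(dgetrs)("N", &n, &nrhs, LU.begin(), &n,
                   const_cast<int*>(ipiv.begin()), X.begin(), &n, &info
                   FCONE);
  if (info != 0) stop("dgetrs failed (%d)", info);
  return X;
}

// Apply the original A to X using its factors: A X = P L U X
// (two triangular multiplies and a row permutation; used for cheap
// residual diagnostics after the in-place factorization).
// [[Rcpp::export]]
NumericMatrix cpp_lu_apply(NumericMatrix LU, IntegerVector ipiv,
                           NumericMatrix X) {
  int n = LU.nrow(), k = X.ncol();
  if (X.nrow() != n) stop("dimension mismatch");
  NumericMatrix Y = clone(X);
  double one = 1.0;
  // Y = U X
  F77_CALL(dtrmm)("L", "U", "N", "N", &n, &k, &one, LU.begin(), &n,
                  Y.begin(), &n FCONE FCONE FCONE FCONE);
  // Y = L Y (unit lower triangular)
  F77_CALL(dtrmm)("L", "L", "N", "U", &n, &k, &one, LU.begin(), &n,
                  Y.begin(), &n FCONE FCONE FCONE FCONE);
  // undo the row interchanges: dgetrf applied them forward, so apply in
  // reverse order
  for (int i = n - 1; i >= 0; --i) {
    int p = ipiv[i] - 1;
    if (p != i)
      for (int j = 0; j < k; ++j) {
        double tmp = Y(i, j); Y(i, j) = Y(p, j); Y(p, j) = tmp;
      }
  }
  return Y;
}
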
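#include <Rcpp.h>
using namespace Rcpp;

// Thomas algorithm for tridiagonal systems. Bands are all length n;
// lower[0] and upper[n-1] are ignored. Errors on a (near-)zero pivot.
// [[Rcpp::export(name = ".thomas_solve")]]
NumericVector thomas_solve(NumericVector lower, NumericVector diag,
                           NumericVector upper, NumericVector rhs) {
  int n = diag.size();
  if (lower.size() != n || upper.size() != n || rhs.size() != n)
    stop("tridiagonal bands and rhs must all have the same length");
  if (n == 0) return NumericVector(0);

  NumericVector cp(n), dp(n), x(n);
  if (diag[0] == 0.0) stop("zero pivot in tridiagonal solve (row 1)");
  cp[0] = upper[0] / diag[0];
  dp[0] = rhs[0] / diag[0];
  for (int i = 1; i < n; ++i) {
    double denom = diag[i] - lower[i] * cp[i - 1];
    if (denom == 0.0) stop("zero pivot in tridiagonal solve (row %d)", i + 1);
    cp[i] = upper[i] / denom;
    dp[i] = (rhs[i] - lower[i] * dp[i - 1]) / denom;
  }
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i)
    x[i] = dp[i] - cp[i] * x[i + 1];
  return x;
}
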
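#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Thomas algorithm for a tridiagonal system.
// lower: subdiagonal (length n-1), diag: length n, upper: superdiagonal
// (length n-1), rhs: length n. No pivoting; the diffusion matrices assembled
// in R are strictly diagonally dominant.
// [[Rcpp::export]]
NumericVector tridiag_solve_cpp(NumericVector lower, NumericVector diag,
                                NumericVector upper, NumericVector rhs) {
  int n = diag.size();
  if (lower.size() != n - 1 || upper.size() != n - 1 || rhs.size() != n)
    stop("inconsistent tridiagonal system dimensions");
  std::vector<double> cp(n), dp(n);
  cp[0] = upper.size() > 0 ? upper[0] / diag[0] : 0.0;
  dp[0] = rhs[0] / diag[0];
  for (int i = 1; i < n; ++i) {
    double m = diag[i] - lower[i - 1] * cp[i - 1];
    cp[i] = (i < n - 1) ? upper[i] / m : 0.0;
    dp[i] = (rhs[i] - lower[i - 1] * dp[i - 1]) / m;
  }
  NumericVector x(n);
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dp[i] - cp[i] * x[i + 1];
  return x;
}

// 26-connected component labelling of a 3-D logical array (column-major,
// dims = c(nx, ny, nz)). Returns integer labels, 0 for background.
// Iterative flood fill with an explicit stack.
// [[Rcpp::export]]
IntegerVector label_components_26_cpp(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int current = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++current;
    stack.clear();
    stack.push_back(s);
    labels[s] = current;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int k = v / ((R_xlen_t)nx * ny);
      int rem = v - (R_xlen_t)k * nx * ny;
      int j = rem / nx;
      int i = rem - j * nx;
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            R_xlen_t w = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
            if (mask[w] && labels[w] == 0) {
              labels[w] = current;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return labels;
}
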
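// Takahashi selected inversion: given the simplicial Cholesky factor
// L L' = P C P' of the (permuted) mixed-model coefficient matrix, compute
// the entries of (P C P')^{-1} on the sparsity pattern of L. These are
// exactly the entries needed for the EM-REML traces, the per-record
// prediction-variance corrections and the PEV diagonal, without ever
// forming the dense inverse.

#include <Rcpp.h>
using namespace Rcpp;

// lower-bound binary search for row r in [lo, hi) of the CSC row indices;
// returns the position or -1 when absent
static inline int find_in_col(const int *Li, int lo, int hi, int r) {
  const int end = hi;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (Li[mid] < r) lo = mid + 1; else hi = mid;
  }
  return (lo < end && Li[lo] == r) ? lo : -1;
}

// [[Rcpp::export(name = ".takahashi_selinv")]]
NumericVector takahashi_selinv(IntegerVector Lp, IntegerVector Li,
                               NumericVector Lx, int n) {
  const int *lp = Lp.begin(); const int *li = Li.begin();
  const double *lx = Lx.begin();
  NumericVector Zx(Lx.size());
  std::vector<double> d(n);        // D of the LDL' rewrite
  // CHOLMOD stores each column with the diagonal entry first
  for (int j = 0; j < n; ++j) {
    double ljj = lx[lp[j]];
    d[j] = ljj * ljj;
  }
  for (int j = n - 1; j >= 0; --j) {
    int cs = lp[j], ce = lp[j + 1];
    double ljj = lx[cs];
    for (int t = ce - 1; t >= cs; --t) {
      int i = li[t];
      double s = 0.0;
      for (int u = cs + 1; u < ce; ++u) {
        int k = li[u];
        double lkj = lx[u] / ljj;        // unit-L entry
        // fetch Z[max(i,k), min(i,k)]
        int r = i >= k ? i : k, c = i >= k ? k : i;
        int pos = find_in_col(li, lp[c], lp[c + 1], r);
        if (pos < 0)
          stop("selected-inverse pattern miss at (%d, %d)", r + 1, c + 1);
        s += lkj * Zx[pos];
      }
      Zx[t] = (i == j) ? 1.0 / d[j] - s : -s;
    }
  }
  return Zx;
}

// vectorized lookup of Z entries (1-based permuted indices); rows >= cols
// after the caller swaps; errors if a requested entry is off-pattern
// [[Rcpp::export(name = ".selinv_lookup")]]
NumericVector selinv_lookup(IntegerVector Lp, IntegerVector Li,
                            NumericVector Zx, IntegerVector rows,
                            IntegerVector cols) {
  const int *lp = Lp.begin(); const int *li = Li.begin();
  int m = rows.size();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    int r = rows[q] - 1, c = cols[q] - 1;
    if (r < c) { int t = r; r = c; c = t; }
    int pos = find_in_col(li, lp[c], lp[c + 1], r);
    if (pos < 0)
      stop("requested inverse entry (%d, %d) is outside the factor pattern",
           rows[q], cols[q]);
    out[q] = Zx[pos];
  }
  return out;
}
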
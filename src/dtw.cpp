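#include <Rcpp.h>
using namespace Rcpp;

// Accumulated-cost matrix for dynamic time warping.
// D is (n+1) x (m+1): D(0,0) = 0, the rest of the first row and column are
// +Inf, and
//   D(i,j) = cost(a_i, b_j) + min(wd * D(i-1,j-1), wl * D(i,j-1), wv * D(i-1,j))
// with cost either |a-b| or (a-b)^2. The DTW distance is D(n,m).
// [[Rcpp::export(name = ".dtw_cost_matrix")]]
NumericMatrix dtw_cost_matrix(NumericVector a, NumericVector b,
                              NumericVector weights, bool squared) {
  const int n = a.size(), m = b.size();
  const double wd = weights[0], wl = weights[1], wv = weights[2];
  NumericMatrix D(n + 1, m + 1);
  const double inf = R_PosInf;
  for (int j = 1; j <= m; ++j) D(0, j) = inf;
  for (int i = 1; i <= n; ++i) D(i, 0) = inf;
  D(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double c = a[i - 1] - b[j - 1];
      c = squared ? c * c : std::abs(c);
      double diag = wd * D(i - 1, j - 1);
      double left = wl * D(i, j - 1);
      double down = wv * D(i - 1, j);
      double best = diag;
      if (left < best) best = left;
      if (down < best) best = down;
      D(i, j) = c + best;
    }
  }
  return D;
}
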
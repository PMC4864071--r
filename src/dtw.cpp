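#include <Rcpp.h>
using namespace Rcpp;

// Banded cumulative-cost matrix for dynamic time warping with a Sakoe-Chiba
// band |i - j| <= window (indices 0-based over the two sequences). Returns
// the (n+1) x (m+1) dynamic-programming matrix with an infinite border row
// and column; D(i, j) is the minimal cumulative local cost of aligning
// x[0..i-1] with y[0..j-1] over monotone warp paths confined to the band.
// Cells outside the band stay +Inf (unreachable). Step pattern: symmetric,
// unweighted three-move (diagonal, i-step, j-step).
// [[Rcpp::export]]
NumericMatrix dtw_cost_matrix(NumericVector x, NumericVector y,
                              int window, bool squared) {
  const int n = x.size(), m = y.size();
  NumericMatrix D(n + 1, m + 1);
  std::fill(D.begin(), D.end(), R_PosInf);
  D(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) {
    const int jlo = std::max(1, i - window);
    const int jhi = std::min(m, i + window);
    for (int j = jlo; j <= jhi; ++j) {
      double d = std::abs(x[i - 1] - y[j - 1]);
      if (squared) d *= d;
      double best = D(i - 1, j - 1);
      if (D(i - 1, j) < best) best = D(i - 1, j);
      if (D(i, j - 1) < best) best = D(i, j - 1);
      D(i, j) = d + best;
    }
  }
  return D;
}

// DTW distance only (skips materializing the full matrix for long inputs is
// not needed at these sizes; kept separate so spectrum sweeps avoid the R
// round-trip per template). Rows of `templates` are compared against `x`.
// [[Rcpp::export]]
NumericVector dtw_sweep(NumericVector x, NumericMatrix templates,
                        int window, bool squared) {
  const int n = x.size(), m = templates.ncol(), K = templates.nrow();
  NumericVector out(K);
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int k = 0; k < K; ++k) {
    std::fill(prev.begin(), prev.end(), R_PosInf);
    prev[0] = 0.0;
    for (int i = 1; i <= n; ++i) {
      std::fill(cur.begin(), cur.end(), R_PosInf);
      const int jlo = std::max(1, i - window);
      const int jhi = std::min(m, i + window);
      for (int j = jlo; j <= jhi; ++j) {
        double d = std::abs(x[i - 1] - templates(k, j - 1));
        if (squared) d *= d;
        double best = prev[j - 1];
        if (prev[j] < best) best = prev[j];
        if (cur[j - 1] < best) best = cur[j - 1];
        cur[j] = d + best;
      }
      std::swap(prev, cur);
    }
    out[k] = prev[m];
  }
  return out;
}
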
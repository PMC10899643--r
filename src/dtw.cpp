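#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-time-warping cost between two equal- or unequal-length series.
// Local cost: absolute difference. Step pattern: symmetric with the
// diagonal step weighted by `diag_weight` (2 reproduces the classic
// symmetric pattern in which a diagonal move pays the local cost twice).
// `window` < 0 disables the Sakoe-Chiba band.
static double dtw_core(const double* a, int n, const double* b, int m,
                       double diag_weight, int window) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m + 1, INF), cur(m + 1, INF);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int jlo = 1, jhi = m;
    if (window >= 0) {
      jlo = std::max(1, i - window);
      jhi = std::min(m, i + window);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double d = std::fabs(a[i - 1] - b[j - 1]);
      double best = prev[j - 1] + diag_weight * d;      // diagonal
      double up   = prev[j] + d;                        // insertion
      double left = cur[j - 1] + d;                     // deletion
      if (up < best) best = up;
      if (left < best) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".dtw_cost_cpp")]]
double dtw_cost_cpp(NumericVector a, NumericVector b,
                    double diag_weight = 2.0, int window = -1) {
  return dtw_core(a.begin(), a.size(), b.begin(), b.size(),
                  diag_weight, window);
}

// Pairwise DTW distances between the rows of `x` (series along columns).
// [[Rcpp::export(name = ".dtw_pairwise_cpp")]]
NumericMatrix dtw_pairwise_cpp(NumericMatrix x,
                               double diag_weight = 2.0, int window = -1) {
  int n = x.nrow(), m = x.ncol();
  NumericMatrix out(n, n);
  std::vector<double> ri(m), rj(m);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < m; ++k) ri[k] = x(i, k);
    for (int j = i + 1; j < n; ++j) {
      for (int k = 0; k < m; ++k) rj[k] = x(j, k);
      double d = dtw_core(ri.data(), m, rj.data(), m, diag_weight, window);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}

// DTW distances between every row of `x` and every row of `y`.
// [[Rcpp::export(name = ".dtw_cross_cpp")]]
NumericMatrix dtw_cross_cpp(NumericMatrix x, NumericMatrix y,
                            double diag_weight = 2.0, int window = -1) {
  int nx = x.nrow(), ny = y.nrow(), m = x.ncol();
  NumericMatrix out(nx, ny);
  std::vector<double> ri(m), rj(y.ncol());
  for (int i = 0; i < nx; ++i) {
    for (int k = 0; k < m; ++k) ri[k] = x(i, k);
    for (int j = 0; j < ny; ++j) {
      for (int k = 0; k < y.ncol(); ++k) rj[k] = y(j, k);
      out(i, j) = dtw_core(ri.data(), m, rj.data(), y.ncol(),
                           diag_weight, window);
    }
  }
  return out;
}
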
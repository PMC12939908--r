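#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ordered-pair counts for sample entropy: B_m over all N-m+1 embedding
// vectors of length m, B_{m+1} over the N-m vectors of length m+1,
// Chebyshev distance <= r, self-matches excluded. Counts are returned as
// doubles (each unordered pair counted once here; the ordered/unordered
// convention cancels in the ratio).
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nm = n - m + 1;   // number of m-vectors
  double bm = 0.0, bm1 = 0.0;
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
        if (d > r) break;
      }
      if (d <= r) {
        bm += 1.0;
        if (i + m < n && j + m < n) {
          double a = std::fabs(x[i + m] - x[j + m]);
          if (a <= r && a >= 0.0) {
            double d1 = d > a ? d : a;
            if (d1 <= r) bm1 += 1.0;
          }
        }
      }
    }
  }
  return NumericVector::create(bm, bm1);
}

// Unconstrained DTW with absolute-difference local cost and the standard
// boundary initialization D(1,1) = dist(a_1, b_1).
// [[Rcpp::export]]
double dtw_distance_cpp(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m), cur(m);
  prev[0] = std::fabs(a[0] - b[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::fabs(a[0] - b[j]);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + std::fabs(a[i] - b[0]);
    for (int j = 1; j < m; ++j) {
      double best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      if (prev[j - 1] < best) best = prev[j - 1];
      cur[j] = best + std::fabs(a[i] - b[j]);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
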
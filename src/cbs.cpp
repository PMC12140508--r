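#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Max of the circular-binary-segmentation statistic over linear arcs.
// For a segment x[0..n-1], consider arcs (i, j] (0 <= i < j <= n, arc not
// the whole segment) and the two-sample t-like statistic comparing the mean
// inside the arc against the mean outside, standardized by the segment sd.
// The scan uses cumulative sums; arcs longer than max_window are skipped
// (documented speed cap).
// With S0 the mean-centered cumulative sum, the statistic for arc (i, j]
// of length m is |S0[j] - S0[i]| * sqrt(n / (m * (n - m))) / sd, so the
// scan needs one subtraction and one multiply per arc once the
// length-dependent factor is tabulated.
static double max_stat_core(const double *x, int n, int max_window,
                            int *best_i, int *best_j) {
  if (best_i) *best_i = 0;
  if (best_j) *best_j = 0;
  if (n < 2) return 0.0;
  std::vector<double> S0(n + 1, 0.0);
  double mean = 0.0;
  for (int k = 0; k < n; ++k) mean += x[k];
  mean /= n;
  double ss = 0.0;
  for (int k = 0; k < n; ++k) {
    double d = x[k] - mean;
    S0[k + 1] = S0[k] + d;
    ss += d * d;
  }
  double sd = std::sqrt(ss / n);
  if (sd <= 0.0) return 0.0;
  std::vector<double> cfac(n, 0.0);
  for (int m = 1; m < n; ++m) {
    cfac[m] = std::sqrt((double)n / ((double)m * (n - m))) / sd;
  }
  double best = -1.0;
  for (int i = 0; i < n; ++i) {
    int jmax = std::min(n, i + max_window);
    for (int j = i + 1; j <= jmax; ++j) {
      int m = j - i;
      if (m == n) continue;
      double z = std::fabs(S0[j] - S0[i]) * cfac[m];
      if (z > best) {
        best = z;
        if (best_i) *best_i = i;
        if (best_j) *best_j = j;
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
NumericVector cbs_max_stat(NumericVector x, int max_window) {
  int bi = 0, bj = 0;
  double m = max_stat_core(x.begin(), x.size(), max_window, &bi, &bj);
  return NumericVector::create(m, bi, bj);
}

// Permutation p-value for the observed max statistic: the fraction of
// within-segment value shuffles whose max statistic reaches the observed
// one. Shuffling uses R's RNG (seed from R). Early exit: once more than
// alpha * nperm shuffles exceed, the split can no longer be accepted.
// [[Rcpp::export]]
double cbs_perm_pvalue(NumericVector x, double observed, int nperm,
                       double alpha, int max_window) {
  int n = x.size();
  std::vector<double> y(x.begin(), x.end());
  int exceed = 0;
  GetRNGstate();
  for (int p = 0; p < nperm; ++p) {
    for (int k = n - 1; k > 0; --k) {
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(y[idx], y[k]);
    }
    double m = max_stat_core(y.data(), n, max_window, nullptr, nullptr);
    if (m >= observed) {
      ++exceed;
      if ((double)exceed > alpha * nperm) break;
    }
  }
  PutRNGstate();
  return (double)exceed / nperm;
}
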
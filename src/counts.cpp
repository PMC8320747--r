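#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Maximized categorical log-likelihood sum_c n_c * log(n_c / n) of the joint
// distribution over a set of integer-coded columns (0-based codes).
// cols is 0-based column indices into data; levels gives declared
// cardinalities for all columns. Dense tabulation when the joint state space
// is small, hashed otherwise.
// [[Rcpp::export]]
double cat_loglik(const IntegerMatrix& data, const IntegerVector& cols,
                  const IntegerVector& levels) {
  const int n = data.nrow();
  if (n == 0) return 0.0;
  const int k = cols.size();
  if (k == 0) return 0.0;

  double space = 1.0;
  for (int j = 0; j < k; ++j) space *= (double)levels[cols[j]];

  double ll = 0.0;
  const double ln_n = std::log((double)n);

  if (space <= 4.0 * n + 1024.0 && space < 2147483000.0) {
    int sz = (int)space;
    std::vector<int> counts(sz, 0);
    std::vector<int> stride(k);
    int s = 1;
    for (int j = 0; j < k; ++j) { stride[j] = s; s *= levels[cols[j]]; }
    for (int i = 0; i < n; ++i) {
      int idx = 0;
      for (int j = 0; j < k; ++j) idx += stride[j] * data(i, cols[j]);
      counts[idx]++;
    }
    for (int c = 0; c < sz; ++c)
      if (counts[c] > 0) ll += counts[c] * (std::log((double)counts[c]) - ln_n);
  } else {
    std::unordered_map<long long, int> counts;
    counts.reserve(2 * n);
    std::vector<long long> stride(k);
    long long s = 1;
    for (int j = 0; j < k; ++j) { stride[j] = s; s *= levels[cols[j]]; }
    for (int i = 0; i < n; ++i) {
      long long idx = 0;
      for (int j = 0; j < k; ++j) idx += stride[j] * (long long)data(i, cols[j]);
      counts[idx]++;
    }
    for (auto& kv : counts)
      ll += kv.second * (std::log((double)kv.second) - ln_n);
  }
  return ll;
}

// Joint counts over a set of columns, returned as a dense vector in
// column-major mixed-radix order (first column fastest). Used for CPT
// fitting and pairwise tables; caller guarantees a small state space.
// [[Rcpp::export]]
IntegerVector joint_counts(const IntegerMatrix& data, const IntegerVector& cols,
                           const IntegerVector& levels) {
  const int n = data.nrow();
  const int k = cols.size();
  double space = 1.0;
  for (int j = 0; j < k; ++j) space *= (double)levels[cols[j]];
  if (space > 100000000.0)
    stop("joint state space too large for dense counting");
  int sz = (int)space;
  IntegerVector counts(sz);
  std::vector<int> stride(k);
  int s = 1;
  for (int j = 0; j < k; ++j) { stride[j] = s; s *= levels[cols[j]]; }
  for (int i = 0; i < n; ++i) {
    int idx = 0;
    for (int j = 0; j < k; ++j) idx += stride[j] * data(i, cols[j]);
    counts[idx]++;
  }
  return counts;
}
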
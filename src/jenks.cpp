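#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fisher's optimal contiguous partition of sorted values into k classes
// minimising total within-class sum of squared deviations (the "Jenks
// natural breaks" optimisation).  Input must be sorted ascending.
// Returns the 1-based index of the last element of each class.

// [[Rcpp::export]]
IntegerVector cpp_fisher_jenks(NumericVector x, int k) {
  const int n = x.size();
  if (k < 1) stop("k must be >= 1");
  if (n < k) stop("need at least k values");

  // prefix sums for O(1) within-class SSD
  std::vector<long double> s1(n + 1, 0.0L), s2(n + 1, 0.0L);
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + x[i];
    s2[i + 1] = s2[i] + (long double)x[i] * x[i];
  }
  auto ssd = [&](int i, int j) -> long double {  // 0-based inclusive
    const int m = j - i + 1;
    const long double sum = s1[j + 1] - s1[i];
    return (s2[j + 1] - s2[i]) - sum * sum / m;
  };

  // dp[j] = optimal cost of partitioning x[0..j] into the current class count
  std::vector<long double> prev(n), cur(n);
  std::vector<std::vector<int>> split(k, std::vector<int>(n, 0));
  for (int j = 0; j < n; ++j) prev[j] = ssd(0, j);
  for (int c = 1; c < k; ++c) {
    for (int j = 0; j < n; ++j) {
      if (j < c) { cur[j] = 0.0L; split[c][j] = j; continue; }
      long double best = -1.0L;
      int argi = c;
      for (int i = c; i <= j; ++i) {  // class c covers x[i..j]
        const long double v = prev[i - 1] + ssd(i, j);
        if (best < 0.0L || v < best) { best = v; argi = i; }
      }
      cur[j] = best;
      split[c][j] = argi;
    }
    std::swap(prev, cur);
  }

  IntegerVector last(k);
  int j = n - 1;
  for (int c = k - 1; c >= 1; --c) {
    last[c] = j + 1;           // 1-based last index of class c
    j = split[c][j] - 1;       // previous class ends just before the split
  }
  last[0] = j + 1;
  return last;
}
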
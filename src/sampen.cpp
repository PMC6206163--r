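#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy. Returns (A, B): B = number of
// ordered-unordered pairs i < j whose length-m templates are within
// Chebyshev distance r, A = same for length m+1. Self-matches excluded by
// construction.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  double A = 0.0, B = 0.0;
  // pairs of templates starting at i and j, both valid for length m+1
  for (int i = 0; i < n - m; ++i) {
    for (int j = i + 1; j < n - m; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        B += 1.0;
        double dm = std::fabs(x[i + m] - x[j + m]);
        if (dm > d) d = dm;
        if (d <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
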
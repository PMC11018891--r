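#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy (Chebyshev distance <= r,
// self-matches excluded, unordered pairs i < j over the N - m templates
// for which an (m+1)-length template also exists).
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  double A = 0.0, B = 0.0;
  int nt = n - m;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
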
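#include <Rcpp.h>
using namespace Rcpp;

// Template-pair counts for sample entropy.
// B = pairs (i < j) of length-m templates with Chebyshev distance <= r,
// A = the same pairs whose length-(m+1) extensions also match.
// Self-matches are excluded by construction (i < j). Both template start
// indices run over 1..N-m so the (m+1)-th point always exists; this keeps
// the A and B counts over a common index set.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;              // number of (m+1)-capable templates
  double A = 0.0, B = 0.0;
  if (nt < 2 || m < 1 || r <= 0) {
    return NumericVector::create(_["A"] = NA_REAL, _["B"] = NA_REAL);
  }
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
  return NumericVector::create(_["A"] = A, _["B"] = B);
}
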
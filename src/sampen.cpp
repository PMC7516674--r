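#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Count matched template pairs for sample entropy.
//
// For all i < j in 0..(N-m-1), a pair matches at length m when the Chebyshev
// distance between the m-length templates starting at i and j is <= r
// (inclusive). B counts matches at length m, A matches at length m+1.
// Both counts run over the same N-m template start positions so that A/B is
// the conditional probability of an m-match extending to m+1; self-matches
// (i == j) are excluded by construction.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of (m+1)-capable template starts
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match_m = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match_m = false; break; }
      }
      if (!match_m) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
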
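#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman & Moorman convention):
// templates i = 1..N-m for both lengths so the counts are comparable,
// Chebyshev distance, self-matches excluded, unordered pairs counted once.
// [[Rcpp::export]]
List sampen_counts(NumericVector x, int m, double r) {
  const int N = x.size();
  const int M = N - m; // number of templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < M - 1; ++i) {
    for (int j = i + 1; j < M; ++j) {
      double dm = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > dm) dm = dk;
        if (dm > r) break;
      }
      if (dm <= r) {
        B += 1.0;
        double dm1 = std::fabs(x[i + m] - x[j + m]);
        if (dm1 < dm) dm1 = dm;
        if (dm1 <= r) A += 1.0;
      }
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}
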
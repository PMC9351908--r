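#include <Rcpp.h>
using namespace Rcpp;

// Event-synchronous normalized-LMS QRST cancellation.
//
// The reference is an impulse train whose impulses sit kernel_pre before
// each R peak, so a causal FIR kernel of length L spans [-pre, +post)
// around the beat. Because the reference is sparse, each sample update
// touches only the kernel taps under the impulses currently inside the
// filter window, which makes the filter O(N * beats-in-window).
//
// pos0: 0-based advanced impulse positions (sorted ascending, may start <0
// for a beat whose kernel support begins before the record).
// Passes 1..n_passes-1 adapt at mu; the final pass adapts at mu/10 and
// produces the residual (slow adaptation after convergence).
// [[Rcpp::export]]
List esaf_nlms(NumericVector d, IntegerVector pos0, int L, double mu,
               int n_passes, NumericVector w_init) {
  const int N = d.size();
  const int P = pos0.size();
  NumericVector w = clone(w_init);
  NumericVector resid(N);
  const double eps = 1e-12;

  for (int pass = 1; pass <= n_passes; ++pass) {
    const bool last = (pass == n_passes);
    const double mu_p = (last && n_passes > 1) ? mu * 0.1 : mu;
    int lo = 0, hi = -1; // pos0[lo..hi] lie in [n-L+1, n]
    for (int n = 0; n < N; ++n) {
      while (hi + 1 < P && pos0[hi + 1] <= n) ++hi;
      while (lo < P && pos0[lo] < n - L + 1) ++lo;
      double y = 0.0;
      int nact = 0;
      for (int k = lo; k <= hi; ++k) {
        int j = n - pos0[k];
        if (j >= 0 && j < L) { y += w[j]; ++nact; }
      }
      double e = d[n] - y;
      if (nact > 0) {
        double g = mu_p * e / ((double)nact + eps);
        for (int k = lo; k <= hi; ++k) {
          int j = n - pos0[k];
          if (j >= 0 && j < L) w[j] += g;
        }
      }
      if (last) resid[n] = e;
    }
  }
  return List::create(_["residual"] = resid, _["kernel"] = w);
}
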
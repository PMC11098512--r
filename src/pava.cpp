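#include <Rcpp.h>
#include "decay.h"
using namespace Rcpp;

// Euclidean projection of x onto { q : q[i] <= gamma * q[i-1] }.
//
// Equivalent to a weighted decreasing isotonic regression after the change of
// variables z[i] = q[i] / gamma^i (weights gamma^(2i)), but computed with
// per-pool relative offsets so small gamma never underflows. Within a pool
// the constraint is tight, q[t+k] = v * gamma^k, and the pool value solving
// min sum_k (v gamma^k - x[t+k])^2 is v = num/den with
// num = sum_k gamma^k x[t+k], den = sum_k gamma^(2k). Standard left-to-right
// pool-adjacent-violators merging; the merge test between consecutive pools
// A (length lA, value vA) and B (value vB) is vB > gamma^lA * vA.
// [[Rcpp::export]]
NumericVector pava_gamma_decreasing_cpp(NumericVector x, double gamma) {
  int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  if (!(gamma > 0.0 && gamma <= 1.0))
    stop("gamma must lie in (0, 1]");
  pava_gamma_decreasing_core(x.begin(), n, gamma, out.begin());
  return out;
}
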
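#ifndef PHOTODEMIX_DECAY_H
#define PHOTODEMIX_DECAY_H

#include <vector>

// Euclidean projection onto { q : q[i] <= gamma * q[i-1] } via generalized
// pool-adjacent-violators (see pava.cpp for the derivation). Operates in
// place on out[0..n).
inline void pava_gamma_decreasing_core(const double* x, int n, double gamma,
                                       double* out) {
  if (n <= 0) return;
  std::vector<double> num(n), den(n), val(n), glen(n);
  std::vector<int> start(n), len(n);
  int top = -1;
  for (int i = 0; i < n; ++i) {
    ++top;
    num[top] = x[i];
    den[top] = 1.0;
    val[top] = x[i];
    glen[top] = gamma;
    start[top] = i;
    len[top] = 1;
    while (top > 0 && val[top] > glen[top - 1] * val[top - 1]) {
      double gA = glen[top - 1];
      num[top - 1] += gA * num[top];
      den[top - 1] += gA * gA * den[top];
      len[top - 1] += len[top];
      glen[top - 1] = gA * glen[top];
      val[top - 1] = num[top - 1] / den[top - 1];
      --top;
    }
  }
  for (int p = 0; p <= top; ++p) {
    double v = val[p];
    double g = 1.0;
    for (int k = 0; k < len[p]; ++k) {
      out[start[p] + k] = v * g;
      g *= gamma;
    }
  }
}

#endif
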
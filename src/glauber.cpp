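#include <Rcpp.h>
using namespace Rcpp;

// Asynchronous single-site heat-bath updates. One step = pick a uniformly
// random site, resample it to 1 with probability g(W * sum_j C_ij S_j -
// theta_eff) where g(x) = 1/(1 + exp(-eps * x)), regardless of its current
// value. theta_eff is theta (literal field) or theta/2 (consistent with the
// half-theta energy). Uses R's RNG so set.seed() gives bit reproducibility;
// site choice and the Bernoulli draw consume the stream in fixed order.
// Records the state bitmask after every step.
// [[Rcpp::export]]
IntegerVector glauber_chain_cpp(NumericMatrix C, double W, double theta_eff,
                                double eps, int sweeps, IntegerVector init) {
  int n = C.nrow();
  if (n > 31) stop("glauber chain supports at most 31 nodes (bitmask states)");
  long steps = (long)sweeps * n;
  IntegerVector out(steps);
  std::vector<int> s(n);
  std::vector<double> field(n, 0.0); // running local input W * sum C_ij S_j
  for (int i = 0; i < n; ++i) s[i] = init[i];
  for (int i = 0; i < n; ++i) {
    double f = 0.0;
    for (int j = 0; j < n; ++j) f += C(i, j) * s[j];
    field[i] = W * f;
  }
  int mask = 0;
  for (int i = 0; i < n; ++i) if (s[i]) mask |= (1 << i);

  for (long t = 0; t < steps; ++t) {
    int i = (int)(unif_rand() * n);
    if (i == n) i = n - 1;
    double x = field[i] - theta_eff;
    double p1 = 1.0 / (1.0 + std::exp(-eps * x));
    int newv = (unif_rand() < p1) ? 1 : 0;
    if (newv != s[i]) {
      double d = newv - s[i];
      for (int j = 0; j < n; ++j) field[j] += W * C(j, i) * d;
      s[i] = newv;
      mask ^= (1 << i);
    }
    out[t] = mask;
  }
  return out;
}
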
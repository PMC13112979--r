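// Fused AdamW update: one pass over the flattened parameter vector with
// bias-corrected moments and decoupled weight decay.

#include <Rcpp.h>

using namespace Rcpp;

// [[Rcpp::export(name = ".adamwUpdate")]]
List adamwUpdate(NumericVector theta, NumericVector g, NumericVector m,
                 NumericVector v, double lr, double weightDecay,
                 double beta1, double beta2, double eps, int t) {
  const R_xlen_t n = theta.size();
  NumericVector m2(n), v2(n), out(n);
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double mi = beta1 * m[i] + (1.0 - beta1) * g[i];
    const double vi = beta2 * v[i] + (1.0 - beta2) * g[i] * g[i];
    m2[i] = mi;
    v2[i] = vi;
    out[i] = theta[i] - lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps) -
      lr * weightDecay * theta[i];
  }
  return List::create(_["theta"] = out, _["m"] = m2, _["v"] = v2);
}
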
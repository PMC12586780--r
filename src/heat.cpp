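#include <Rcpp.h>
using namespace Rcpp;

// Forward recursion for the two-regime Newtonian heat-exchange model.
//   dTb/dt = k (Ta - Tb) + Tm_dot,  k = k_warm when Ta >= Tb, k_cool otherwise
// scheme 0: forward Euler at step dt
// scheme 1: exact exponential step (Ta held constant over each step)
// The regime is keyed to `state`: the simulated Tb by default, or an observed
// trace (tb_ref, same length as ta) when supplied.
// [[Rcpp::export]]
NumericVector predict_tb_cpp(const NumericVector& ta, double dt,
                             double k_warm, double k_cool, double tm_dot,
                             double tb0, int scheme,
                             const NumericVector& tb_ref) {
  const int n = ta.size();
  NumericVector tb(n);
  if (n == 0) return tb;
  tb[0] = tb0;
  const bool use_ref = tb_ref.size() == n;
  for (int t = 0; t < n - 1; ++t) {
    const double state = use_ref ? tb_ref[t] : tb[t];
    const double k = (ta[t] >= state) ? k_warm : k_cool;
    if (scheme == 0) {
      tb[t + 1] = tb[t] + dt * (k * (ta[t] - tb[t]) + tm_dot);
    } else {
      if (k > 0.0) {
        const double eq = ta[t] + tm_dot / k;
        tb[t + 1] = eq + (tb[t] - eq) * std::exp(-k * dt);
      } else {
        tb[t + 1] = tb[t] + tm_dot * dt;  // k -> 0 limit
      }
    }
  }
  return tb;
}
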
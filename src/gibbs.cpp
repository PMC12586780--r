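#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double rinvgamma(double shape, double rate) {
  // R::rgamma is parameterised by (shape, scale)
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// Blocked Gibbs sampler for the Gaussian phylogenetic mixed model
//   y = X beta + Z u + Z s + e
// with u ~ N(0, sig2p * A) (phylogenetic, Brownian covariance A),
// s ~ N(0, sig2s * I) (species-level, intraspecific replicate structure),
// e ~ N(0, sig2e * I). Z maps individuals to species (sp, 0-based).
// Priors: beta ~ N(0, beta_var * I); inverse-gamma(ig_shape, ig_rate) on all
// three variances. All conditionals are closed-form. Uses R's RNG, so
// set.seed() on the R side makes runs reproducible.
// [[Rcpp::export]]
List gibbs_pmm_cpp(const arma::vec& y, const arma::mat& X,
                   const arma::uvec& sp, const arma::mat& Ainv,
                   int n_iter, int burn, int thin,
                   double beta_var, double ig_shape, double ig_rate) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int S = Ainv.n_rows;
  const double LOG2PI = std::log(2.0 * M_PI);

  arma::vec beta(p, arma::fill::zeros);
  arma::vec u(S, arma::fill::zeros);
  arma::vec s(S, arma::fill::zeros);
  double vy = arma::var(y);
  if (!(vy > 0.0)) vy = 1.0;
  double sig2p = 0.1 * vy, sig2s = 0.1 * vy, sig2e = vy;

  arma::vec nsp(S, arma::fill::zeros);
  for (int i = 0; i < n; ++i) nsp[sp[i]] += 1.0;

  const arma::mat XtX = X.t() * X;

  const int kept = (n_iter - burn) / thin;
  arma::mat B(kept, p), U(kept, S), Sdraw(kept, S), V(kept, 3);
  arma::vec dev(kept);
  int idx = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // --- beta | rest ---
    arma::vec r(n);
    for (int i = 0; i < n; ++i) r[i] = y[i] - u[sp[i]] - s[sp[i]];
    arma::mat Pb = XtX / sig2e;
    Pb.diag() += 1.0 / beta_var;
    arma::vec rhs_b = X.t() * r / sig2e;
    arma::vec mb = arma::solve(Pb, rhs_b, arma::solve_opts::likely_sympd);
    arma::mat Rb = arma::chol(Pb);
    arma::vec zb(p);
    for (int j = 0; j < p; ++j) zb[j] = R::norm_rand();
    beta = mb + arma::solve(arma::trimatu(Rb), zb);

    const arma::vec xb = X * beta;

    // --- u | rest ---
    arma::vec ru(S, arma::fill::zeros);
    for (int i = 0; i < n; ++i) ru[sp[i]] += y[i] - xb[i] - s[sp[i]];
    arma::mat Pu = Ainv / sig2p;
    Pu.diag() += nsp / sig2e;
    arma::vec mu = arma::solve(Pu, ru / sig2e, arma::solve_opts::likely_sympd);
    arma::mat Ru = arma::chol(Pu);
    arma::vec zu(S);
    for (int j = 0; j < S; ++j) zu[j] = R::norm_rand();
    u = mu + arma::solve(arma::trimatu(Ru), zu);

    // --- s | rest (diagonal precision: elementwise) ---
    arma::vec rs(S, arma::fill::zeros);
    for (int i = 0; i < n; ++i) rs[sp[i]] += y[i] - xb[i] - u[sp[i]];
    for (int j = 0; j < S; ++j) {
      const double prec = nsp[j] / sig2e + 1.0 / sig2s;
      const double mean = (rs[j] / sig2e) / prec;
      s[j] = mean + R::norm_rand() / std::sqrt(prec);
    }

    // --- variances ---
    const double quad_u = arma::as_scalar(u.t() * Ainv * u);
    sig2p = rinvgamma(ig_shape + 0.5 * S, ig_rate + 0.5 * quad_u);
    sig2s = rinvgamma(ig_shape + 0.5 * S, ig_rate + 0.5 * arma::dot(s, s));
    arma::vec e(n);
    for (int i = 0; i < n; ++i) e[i] = y[i] - xb[i] - u[sp[i]] - s[sp[i]];
    sig2e = rinvgamma(ig_shape + 0.5 * n, ig_rate + 0.5 * arma::dot(e, e));

    if (it > burn && ((it - burn) % thin == 0) && idx < kept) {
      B.row(idx) = beta.t();
      U.row(idx) = u.t();
      Sdraw.row(idx) = s.t();
      V(idx, 0) = sig2p;
      V(idx, 1) = sig2s;
      V(idx, 2) = sig2e;
      dev[idx] = n * (LOG2PI + std::log(sig2e)) + arma::dot(e, e) / sig2e;
      ++idx;
    }
  }

  return List::create(_["beta"] = B, _["u"] = U, _["s"] = Sdraw,
                      _["sigma2"] = V, _["deviance"] = dev);
}
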
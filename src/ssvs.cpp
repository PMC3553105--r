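// Polya-Gamma augmented Gibbs sampler for spike-and-slab logistic SSVS.
//
// PG(1, z) draws use the alternating-series rejection sampler of
// Polson, Scott & Windle (exact; no truncation error). All randomness goes
// through R's RNG so set.seed() gives bit-identical chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TRUNC = 0.64;  // series crossover point for J*(1,z)

// series coefficients a_n(x) of the J*(1,0) density
static double a_coef(int n, double x) {
  double k = n + 0.5;
  if (x > TRUNC)
    return M_PI * k * std::exp(-0.5 * k * k * M_PI * M_PI * x);
  return M_PI * k * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * k * k / x);
}

// inverse-Gaussian(mu = 1/z, lambda = 1) CDF at t
static double pigauss(double t, double z) {
  double rt = std::sqrt(1.0 / t);
  double a = rt * (t * z - 1.0);
  double b = -rt * (t * z + 1.0);
  return R::pnorm(a, 0, 1, 1, 0) + std::exp(2.0 * z) * R::pnorm(b, 0, 1, 1, 0);
}

// draw from IG(1/z, 1) truncated to (0, TRUNC)
static double rtigauss(double z) {
  double t = TRUNC, x;
  if (z < 1.0 / t) {  // large-mean regime: inverse-chi-square proposal
    for (;;) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  }
  double mu = 1.0 / z;
  do {
    double y = R::norm_rand();
    y = y * y;
    x = mu + 0.5 * mu * mu * y -
        0.5 * mu * std::sqrt(4.0 * mu * y + mu * mu * y * y);
    if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
  } while (x >= t);
  return x;
}

// one PG(1, z) draw
static double rpg1(double zin) {
  double z = std::fabs(zin) * 0.5;
  double fz = M_PI * M_PI * 0.125 + 0.5 * z * z;
  double p = (M_PI / (2.0 * fz)) * std::exp(-fz * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  for (;;) {
    double x;
    if (R::unif_rand() < p / (p + q))
      x = TRUNC + R::exp_rand() / fz;
    else
      x = rtigauss(z);
    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x * 0.25;
      } else {
        s += a_coef(n, x);
        if (y > s) break;  // reject, propose again
      }
    }
  }
}

//' Polya-Gamma PG(1, z) random draws
//'
//' Exact draws from the Polya-Gamma distribution PG(1, z) via the
//' alternating-series rejection sampler; uses R's RNG stream.
//'
//' @param n number of draws.
//' @param z tilting parameters (recycled to length \code{n}).
//' @return numeric vector of draws.
//' @export
// [[Rcpp::export]]
NumericVector rpg(int n, NumericVector z) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i % z.size()]);
  return out;
}

// log P(gamma_j = 1 | beta_sel, gamma_-j): spike/slab density ratio using
// the precomputed R^{-1}. u = D^{-1} beta_sel.
static double gamma_logit(int j, const arma::vec& u, const arma::vec& beta_s,
                          const arma::mat& Rinv, double tau, double cc,
                          double pj) {
  double u1 = beta_s[j] / (cc * tau);  // included
  double u0 = beta_s[j] / tau;         // excluded
  double w = arma::dot(Rinv.col(j), u) - Rinv(j, j) * u[j];
  double q1 = Rinv(j, j) * u1 * u1 + 2.0 * u1 * w;
  double q0 = Rinv(j, j) * u0 * u0 + 2.0 * u0 * w;
  double logratio = -std::log(cc) - 0.5 * (q1 - q0);
  if (pj >= 1.0) return INFINITY;
  return std::log(pj / (1.0 - pj)) + logratio;
}

// [[Rcpp::export]]
List ssvs_chain_pg(const arma::vec& y, const arma::mat& Xf,
                   const arma::mat& Xs, const arma::mat& Rinv,
                   double tau, double cc, const arma::vec& pincl,
                   double sigma_forced, int n_iter, int n_burn, int thin,
                   arma::vec gamma, arma::vec beta) {
  const int n = y.n_elem, f = Xf.n_cols, m = Xs.n_cols, d = f + m;
  arma::mat X(n, d);
  if (f > 0) X.cols(0, f - 1) = Xf;
  if (m > 0) X.cols(f, d - 1) = Xs;
  const arma::vec kappa = y - 0.5;
  const arma::vec Xtk = X.t() * kappa;
  const double prec_forced = 1.0 / (sigma_forced * sigma_forced);

  int n_keep = (n_iter - n_burn) / thin;
  arma::mat beta_draws(n_keep, d);
  arma::imat gamma_draws(n_keep, m);
  int keep = 0;
  arma::vec u(m);

  for (int it = 1; it <= n_iter; ++it) {
    // --- omega | beta ---
    arma::vec eta = X * beta;
    arma::vec omega(n);
    for (int i = 0; i < n; ++i) omega[i] = rpg1(eta[i]);

    // --- beta | omega, gamma ---
    arma::mat Xw = X.each_col() % arma::sqrt(omega);
    arma::mat M = Xw.t() * Xw;   // X' Omega X via symmetric rank-k update
    for (int k = 0; k < f; ++k) M(k, k) += prec_forced;
    if (m > 0) {
      arma::vec dinv(m);
      for (int j = 0; j < m; ++j)
        dinv[j] = 1.0 / (tau * (gamma[j] > 0.5 ? cc : 1.0));
      // prior precision of beta_sel: D^{-1} R^{-1} D^{-1}
      M.submat(f, f, d - 1, d - 1) +=
          Rinv % (dinv * dinv.t());
    }
    arma::mat L = arma::chol(M, "lower");
    arma::vec mu = arma::solve(arma::trimatu(L.t()),
                               arma::solve(arma::trimatl(L), Xtk));
    arma::vec zdraw(d);
    for (int k = 0; k < d; ++k) zdraw[k] = R::norm_rand();
    beta = mu + arma::solve(arma::trimatu(L.t()), zdraw);

    // --- gamma | beta (random scan) ---
    if (m > 0) {
      arma::vec beta_s = beta.subvec(f, d - 1);
      for (int j = 0; j < m; ++j)
        u[j] = beta_s[j] / (tau * (gamma[j] > 0.5 ? cc : 1.0));
      // Fisher-Yates permutation from R's RNG
      arma::ivec ord(m);
      for (int j = 0; j < m; ++j) ord[j] = j;
      for (int j = m - 1; j > 0; --j) {
        int k = (int)std::floor(R::unif_rand() * (j + 1));
        std::swap(ord[j], ord[k]);
      }
      for (int jj = 0; jj < m; ++jj) {
        int j = ord[jj];
        double lg = gamma_logit(j, u, beta_s, Rinv, tau, cc, pincl[j]);
        double pr = std::isinf(lg) ? 1.0 : 1.0 / (1.0 + std::exp(-lg));
        gamma[j] = (R::unif_rand() < pr) ? 1.0 : 0.0;
        u[j] = beta_s[j] / (tau * (gamma[j] > 0.5 ? cc : 1.0));
      }
    }

    if (it > n_burn && ((it - n_burn) % thin == 0) && keep < n_keep) {
      beta_draws.row(keep) = beta.t();
      for (int j = 0; j < m; ++j)
        gamma_draws(keep, j) = (int)(gamma[j] > 0.5);
      ++keep;
    }
  }
  return List::create(_["beta"] = beta_draws, _["gamma"] = gamma_draws);
}
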
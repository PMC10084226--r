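// Gibbs sampler for the contrast-based random-effects consistency model.
//
// Likelihood: y_i ~ N(delta_i, S_i) per trial; delta_i ~ N(X_i d, tau^2 C_i)
// with C_i = (I + J)/2 so that contrasts sharing a baseline arm have
// heterogeneity correlation 1/2. Priors: d ~ N(0, sd_d^2 I),
// tau ~ Uniform(0, upper). d and delta have conjugate normal full
// conditionals; tau is updated by a stepping-out + shrinkage slice sampler
// on its (bounded) full conditional.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// log full conditional of tau up to a constant:
//   -M log(tau) - Q / (2 tau^2),  tau in (0, upper)
static inline double tau_logpost(double tau, double M, double Q) {
  return -M * std::log(tau) - Q / (2.0 * tau * tau);
}

static double slice_tau(double tau0, double M, double Q, double upper) {
  const double w = std::max(0.05, std::sqrt(Q / std::max(M, 1.0)) / 2.0);
  const double eps = 1e-8;
  double logy = tau_logpost(tau0, M, Q) - R::rexp(1.0);
  double L = tau0 - w * R::runif(0.0, 1.0);
  double Rr = L + w;
  while (L > eps && tau_logpost(L, M, Q) > logy) L -= w;
  while (Rr < upper && tau_logpost(Rr, M, Q) > logy) Rr += w;
  L = std::max(L, eps);
  Rr = std::min(Rr, upper);
  for (int it = 0; it < 1000; ++it) {
    double prop = R::runif(L, Rr);
    if (tau_logpost(prop, M, Q) > logy) return prop;
    if (prop < tau0) L = prop; else Rr = prop;
  }
  return tau0;  // shrinkage degenerated; keep current value
}

// [[Rcpp::export(name = ".nma_gibbs")]]
arma::mat nma_gibbs(const List& y_list, const List& Sinv_list,
                    const List& Cinv_list, const List& X_list,
                    int n_iter, int n_burn, double prior_d_sd,
                    double tau_upper, const arma::vec& d_init,
                    double tau_init) {
  const int n_tr = y_list.size();
  const int K1 = d_init.n_elem;  // number of basic parameters

  std::vector<arma::vec> y(n_tr);
  std::vector<arma::mat> Sinv(n_tr), Cinv(n_tr), X(n_tr);
  std::vector<arma::vec> Sinv_y(n_tr);
  double M = 0.0;
  arma::mat A(K1, K1, arma::fill::zeros);  // sum X' Cinv X
  for (int i = 0; i < n_tr; ++i) {
    y[i] = as<arma::vec>(y_list[i]);
    Sinv[i] = as<arma::mat>(Sinv_list[i]);
    Cinv[i] = as<arma::mat>(Cinv_list[i]);
    X[i] = as<arma::mat>(X_list[i]);
    Sinv_y[i] = Sinv[i] * y[i];
    M += y[i].n_elem;
    A += X[i].t() * Cinv[i] * X[i];
  }

  arma::vec d = d_init;
  double tau = tau_init;
  std::vector<arma::vec> delta(n_tr);
  for (int i = 0; i < n_tr; ++i) delta[i] = y[i];

  const double prior_prec = 1.0 / (prior_d_sd * prior_d_sd);
  const int n_keep = n_iter - n_burn;
  arma::mat out(n_keep, K1 + 1);

  for (int iter = 0; iter < n_iter; ++iter) {
    const double itau2 = 1.0 / (tau * tau);

    // delta_i | y_i, d, tau  (conjugate normal)
    arma::vec rhs_d(K1, arma::fill::zeros);
    double Q = 0.0;
    for (int i = 0; i < n_tr; ++i) {
      arma::mat prec = Sinv[i] + itau2 * Cinv[i];
      arma::mat U = arma::chol(prec);  // prec = U'U
      arma::vec mu = arma::solve(arma::trimatu(U),
                     arma::solve(arma::trimatl(U.t()),
                                 Sinv_y[i] + itau2 * (Cinv[i] * (X[i] * d))));
      arma::vec z(mu.n_elem);
      for (arma::uword j = 0; j < z.n_elem; ++j) z(j) = R::norm_rand();
      delta[i] = mu + arma::solve(arma::trimatu(U), z);
      rhs_d += X[i].t() * (Cinv[i] * delta[i]);
    }

    // d | delta, tau  (conjugate normal)
    arma::mat P = itau2 * A;
    P.diag() += prior_prec;
    arma::mat U = arma::chol(P);
    arma::vec mu = arma::solve(arma::trimatu(U),
                   arma::solve(arma::trimatl(U.t()), itau2 * rhs_d));
    arma::vec z(K1);
    for (int j = 0; j < K1; ++j) z(j) = R::norm_rand();
    d = mu + arma::solve(arma::trimatu(U), z);

    // tau | delta, d  (slice)
    for (int i = 0; i < n_tr; ++i) {
      arma::vec r = delta[i] - X[i] * d;
      Q += arma::as_scalar(r.t() * Cinv[i] * r);
    }
    tau = slice_tau(tau, M, Q, tau_upper);

    if (iter >= n_burn) {
      out(iter - n_burn, arma::span(0, K1 - 1)) = d.t();
      out(iter - n_burn, K1) = tau;
    }
  }
  return out;
}
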
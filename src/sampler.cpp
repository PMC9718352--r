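#include <Rcpp.h>
using namespace Rcpp;

// Hierarchical Bernoulli-beta model, one MCMC chain.
//
//   k_s ~ Binomial(n_s, theta_s)
//   theta_s ~ Beta(mu*(kappa - floor) + 1, (1 - mu)*(kappa - floor) + 1)
//   mu ~ Beta(mu_a, mu_b),  (kappa - floor) ~ Gamma(shape, rate)
//
// Metropolis-within-Gibbs with Gaussian random-walk proposals on the
// unconstrained scale: logit(mu), log(kappa - floor), logit(theta_s).
// Proposal scales adapt in batches during warmup only (target acceptance
// 0.44 per scalar), then stay frozen so the post-warmup chain is a valid
// Markov chain. Uses R's RNG: seeding happens on the R side.

static inline double log_sigmoid(double x) {
  // log(1/(1+exp(-x))) without overflow
  if (x > 0.0) return -log1p(std::exp(-x));
  return x - log1p(std::exp(x));
}

// log density of theta-block terms that depend on theta_s, as a function of
// logit(theta_s), including the logit Jacobian. Beta normalizer omitted
// (constant in theta).
static inline double lp_theta(double lth, double ks, double ns,
                              double a, double b) {
  double lt = log_sigmoid(lth);     // log(theta)
  double l1 = log_sigmoid(-lth);    // log(1 - theta)
  return (ks + a) * lt + (ns - ks + b) * l1;
}

// sum over subjects of full Beta(theta_s | a, b) log densities
static double sum_beta_logdens(const std::vector<double>& lt,
                               const std::vector<double>& l1,
                               double a, double b) {
  double s = 0.0;
  double lB = R::lbeta(a, b);
  for (size_t i = 0; i < lt.size(); ++i)
    s += (a - 1.0) * lt[i] + (b - 1.0) * l1[i] - lB;
  return s;
}

// [[Rcpp::export]]
List bernbeta_chain(NumericVector k, NumericVector n,
                    int n_iter, int n_warmup,
                    double mu_a, double mu_b,
                    double kap_shape, double kap_rate, double kap_floor,
                    double init_mu, double init_kappa,
                    NumericVector init_theta,
                    bool fix_mu, bool fix_kappa,
                    double scale_mu, double scale_kappa,
                    double scale_theta, int adapt_batch) {
  const int S = k.size();
  RNGScope scope;

  // state on the unconstrained scale
  double lmu = std::log(init_mu) - std::log1p(-init_mu);
  double lka = std::log(init_kappa - kap_floor + 1e-12);
  std::vector<double> lth(S), lt(S), l1(S);
  for (int s = 0; s < S; ++s) {
    double th = init_theta[s];
    lth[s] = std::log(th) - std::log1p(-th);
    lt[s] = log_sigmoid(lth[s]);
    l1[s] = log_sigmoid(-lth[s]);
  }
  double mu = init_mu, kap = init_kappa;
  double a = mu * (kap - kap_floor) + 1.0;
  double b = (1.0 - mu) * (kap - kap_floor) + 1.0;

  std::vector<double> sth(S, scale_theta);
  double smu = scale_mu, ska = scale_kappa;

  NumericMatrix draws(n_iter, 2 + S);
  std::vector<long> acc_th(S, 0), try_th(S, 0);
  long acc_mu = 0, try_mu = 0, acc_ka = 0, try_ka = 0;
  std::vector<long> bacc_th(S, 0);
  long bacc_mu = 0, bacc_ka = 0;
  int batch_no = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- per-subject theta updates ---
    for (int s = 0; s < S; ++s) {
      double prop = lth[s] + sth[s] * norm_rand();
      double cur = lp_theta(lth[s], k[s], n[s], a, b);
      double nw  = lp_theta(prop,  k[s], n[s], a, b);
      ++try_th[s];
      if (std::log(unif_rand()) < nw - cur) {
        lth[s] = prop;
        lt[s] = log_sigmoid(prop);
        l1[s] = log_sigmoid(-prop);
        ++acc_th[s];
        ++bacc_th[s];
      }
    }

    // --- mu update (logit scale; Beta prior + logit Jacobian) ---
    if (!fix_mu) {
      double prop = lmu + smu * norm_rand();
      double mu_p = 1.0 / (1.0 + std::exp(-prop));
      double a_p = mu_p * (kap - kap_floor) + 1.0;
      double b_p = (1.0 - mu_p) * (kap - kap_floor) + 1.0;
      double cur = sum_beta_logdens(lt, l1, a, b)
        + mu_a * log_sigmoid(lmu) + mu_b * log_sigmoid(-lmu);
      double nw = sum_beta_logdens(lt, l1, a_p, b_p)
        + mu_a * log_sigmoid(prop) + mu_b * log_sigmoid(-prop);
      ++try_mu;
      if (std::log(unif_rand()) < nw - cur) {
        lmu = prop; mu = mu_p; a = a_p; b = b_p;
        ++acc_mu; ++bacc_mu;
      }
    }

    // --- kappa update (log(kappa - floor) scale; Gamma prior + Jacobian) ---
    if (!fix_kappa) {
      double prop = lka + ska * norm_rand();
      double ex_p = std::exp(prop);
      double kap_p = kap_floor + ex_p;
      double a_p = mu * ex_p + 1.0;
      double b_p = (1.0 - mu) * ex_p + 1.0;
      double ex = std::exp(lka);
      double cur = sum_beta_logdens(lt, l1, a, b)
        + kap_shape * lka - kap_rate * ex;
      double nw = sum_beta_logdens(lt, l1, a_p, b_p)
        + kap_shape * prop - kap_rate * ex_p;
      ++try_ka;
      if (std::log(unif_rand()) < nw - cur) {
        lka = prop; kap = kap_p; a = a_p; b = b_p;
        ++acc_ka; ++bacc_ka;
      }
    }

    // --- batch adaptation during warmup ---
    if (it < n_warmup && (it + 1) % adapt_batch == 0) {
      ++batch_no;
      double delta = std::min(0.05, 1.0 / std::sqrt((double)batch_no));
      for (int s = 0; s < S; ++s) {
        double rate = (double)bacc_th[s] / adapt_batch;
        sth[s] *= std::exp(rate > 0.44 ? delta : -delta);
        bacc_th[s] = 0;
      }
      if (!fix_mu) {
        smu *= std::exp(((double)bacc_mu / adapt_batch) > 0.44 ? delta : -delta);
        bacc_mu = 0;
      }
      if (!fix_kappa) {
        ska *= std::exp(((double)bacc_ka / adapt_batch) > 0.44 ? delta : -delta);
        bacc_ka = 0;
      }
    }

    draws(it, 0) = mu;
    draws(it, 1) = kap;
    for (int s = 0; s < S; ++s)
      draws(it, 2 + s) = 1.0 / (1.0 + std::exp(-lth[s]));
  }

  NumericVector acc(2 + S);
  acc[0] = fix_mu ? NA_REAL : (double)acc_mu / try_mu;
  acc[1] = fix_kappa ? NA_REAL : (double)acc_ka / try_ka;
  for (int s = 0; s < S; ++s) acc[2 + s] = (double)acc_th[s] / try_th[s];

  return List::create(_["draws"] = draws, _["accept"] = acc,
                      _["scale_mu"] = smu, _["scale_kappa"] = ska);
}
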
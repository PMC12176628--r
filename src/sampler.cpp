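// Adaptive Metropolis-within-Gibbs sampler for the package's hierarchical
// regression layer. Families: gaussian (identity), negative binomial (log),
// beta / zero-inflated beta / zero-one-inflated beta (logit). Random
// structure: independent intercepts and year-slopes at up to two nested
// grouping levels. Priors: Normal(0, s) on coefficients, half-Normal on
// scale/dispersion parameters (sampled on the log scale with Jacobian),
// Beta(1,1) on inflation probabilities (sampled on the logit scale).
#include <Rcpp.h>
using namespace Rcpp;

static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// family codes: 0 gaussian, 1 negbinomial_log, 2 beta_logit,
//               3 zi_beta_logit, 4 zoi_beta_logit
static double lp_obs(double y, double eta, const std::vector<double> &aux,
                     int family) {
  switch (family) {
  case 0: {
    return R::dnorm(y, eta, std::exp(aux[0]), 1);
  }
  case 1: {
    return R::dnbinom_mu(y, std::exp(aux[0]), std::exp(eta), 1);
  }
  case 2: {
    double mu = inv_logit(eta), phi = std::exp(aux[0]);
    return R::dbeta(y, mu * phi, (1.0 - mu) * phi, 1);
  }
  case 3: {
    double zi = inv_logit(aux[1]);
    if (y <= 0.0) return std::log(zi);
    double mu = inv_logit(eta), phi = std::exp(aux[0]);
    return std::log(1.0 - zi) + R::dbeta(y, mu * phi, (1.0 - mu) * phi, 1);
  }
  case 4: {
    double zoi = inv_logit(aux[1]), coi = inv_logit(aux[2]);
    if (y <= 0.0) return std::log(zoi) + std::log(1.0 - coi);
    if (y >= 1.0) return std::log(zoi) + std::log(coi);
    double mu = inv_logit(eta), phi = std::exp(aux[0]);
    return std::log(1.0 - zoi) + R::dbeta(y, mu * phi, (1.0 - mu) * phi, 1);
  }
  }
  return NA_REAL;
}

struct Adapt {
  std::vector<double> lstep; // log proposal sd
  std::vector<int> n;        // adaptation counter
  void init(size_t k, double s0) {
    lstep.assign(k, std::log(s0));
    n.assign(k, 0);
  }
  double step(size_t i) { return std::exp(lstep[i]); }
  void tune(size_t i, bool accepted, bool warm) {
    if (!warm) return;
    n[i]++;
    double gain = 1.0 / std::sqrt((double)n[i] + 3.0);
    lstep[i] += gain * ((accepted ? 1.0 : 0.0) - 0.44);
    if (lstep[i] < -10) lstep[i] = -10;
    if (lstep[i] > 6) lstep[i] = 6;
  }
};

// The fixed-effects block is sampled in a QR-preconditioned basis: X here is
// the (scaled) orthogonal factor and Rinv maps sampled coordinates back to
// the coefficient scale, where the Normal(0, beta_prior_sd) prior applies.
// [[Rcpp::export(name = ".mwg_sample")]]
List mwg_sample(NumericVector y, NumericMatrix X, int family,
                NumericVector tvec, IntegerVector g1, IntegerVector g2,
                LogicalVector re_flags, // u1_int, u1_slope, u2_int, u2_slope
                int n_iter, int n_warmup, int thin, double beta_prior_sd,
                double sd_prior_scale, double aux_prior_scale,
                NumericVector beta_init, NumericVector aux_init,
                NumericMatrix Rinv) {
  const int n = y.size(), p = X.ncol();
  const bool has_u1 = re_flags[0], has_u1s = re_flags[1];
  const bool has_u2 = re_flags[2], has_u2s = re_flags[3];
  const int J1 = (has_u1 || has_u1s) ? (g1.size() ? max(g1) + 1 : 0) : 0;
  const int J2 = (has_u2 || has_u2s) ? (g2.size() ? max(g2) + 1 : 0) : 0;
  const int n_aux = aux_init.size();

  // row indices per group
  std::vector<std::vector<int>> rows1(std::max(J1, 1)), rows2(std::max(J2, 1));
  if (J1 > 0) for (int i = 0; i < n; i++) rows1[g1[i]].push_back(i);
  if (J2 > 0) for (int i = 0; i < n; i++) rows2[g2[i]].push_back(i);

  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> aux(aux_init.begin(), aux_init.end());
  std::vector<double> u1(J1, 0.0), u1s(J1, 0.0), u2(J2, 0.0), u2s(J2, 0.0);
  // log sds for active RE blocks
  double ls_u1 = std::log(0.5), ls_u1s = std::log(0.1);
  double ls_u2 = std::log(0.5), ls_u2s = std::log(0.1);

  NumericVector eta(n);
  for (int i = 0; i < n; i++) {
    double e = 0.0;
    for (int j = 0; j < p; j++) e += X(i, j) * beta[j];
    eta[i] = e;
  }

  auto ll_all = [&](void) {
    double s = 0.0;
    for (int i = 0; i < n; i++) s += lp_obs(y[i], eta[i], aux, family);
    return s;
  };
  auto ll_rows = [&](const std::vector<int> &idx) {
    double s = 0.0;
    for (int i : idx) s += lp_obs(y[i], eta[i], aux, family);
    return s;
  };
  // half-normal prior on exp(laux) with log Jacobian; inflation probs uniform
  auto lp_aux = [&](int k, double v) {
    if (k == 0) { // scale / dispersion parameter on log scale
      double s = std::exp(v);
      return R::dnorm(s, 0.0, aux_prior_scale, 1) + v;
    }
    double pr = inv_logit(v); // Beta(1,1) + logit Jacobian
    return std::log(pr) + std::log(1.0 - pr);
  };
  auto lp_logsd = [&](double lsd) {
    double s = std::exp(lsd);
    return R::dnorm(s, 0.0, sd_prior_scale, 1) + lsd;
  };

  Adapt a_beta, a_aux, a_u1, a_u1s, a_u2, a_u2s, a_sd;
  a_beta.init(p, 0.1);
  a_aux.init(n_aux, 0.2);
  a_u1.init(J1, 0.3);
  a_u1s.init(J1, 0.05);
  a_u2.init(J2, 0.3);
  a_u2s.init(J2, 0.05);
  a_sd.init(4, 0.3);

  const int n_keep = (n_iter - n_warmup) / thin;
  const int n_sd = (has_u1 ? 1 : 0) + (has_u1s ? 1 : 0) + (has_u2 ? 1 : 0) +
                   (has_u2s ? 1 : 0);
  NumericMatrix draws(n_keep, p + n_aux + n_sd);
  NumericVector u1_mean(J1), u1s_mean(J1), u2_mean(J2), u2s_mean(J2);
  int kept = 0;
  double acc_beta = 0.0, prop_beta = 0.0;

  RNGScope scope;
  double cur_ll = ll_all();

  for (int it = 0; it < n_iter; it++) {
    bool warm = it < n_warmup;

    // fixed effects, component-wise random walk in the orthogonal basis;
    // the prior is evaluated on the back-transformed coefficients
    auto lp_beta_prior = [&](const std::vector<double> &th) {
      double s = 0.0;
      for (int i = 0; i < p; i++) {
        double b = 0.0;
        for (int j = 0; j < p; j++) b += Rinv(i, j) * th[j];
        s += R::dnorm(b, 0.0, beta_prior_sd, 1);
      }
      return s;
    };
    for (int j = 0; j < p; j++) {
      double d = R::norm_rand() * a_beta.step(j);
      for (int i = 0; i < n; i++) eta[i] += X(i, j) * d;
      double new_ll = ll_all();
      double pr0 = lp_beta_prior(beta);
      beta[j] += d;
      double dprior = lp_beta_prior(beta) - pr0;
      beta[j] -= d;
      bool acc = std::log(R::unif_rand()) < (new_ll - cur_ll + dprior);
      if (acc) {
        beta[j] += d;
        cur_ll = new_ll;
      } else {
        for (int i = 0; i < n; i++) eta[i] -= X(i, j) * d;
      }
      a_beta.tune(j, acc, warm);
      prop_beta += 1.0;
      if (acc) acc_beta += 1.0;
    }

    // auxiliary family parameters
    for (int k = 0; k < n_aux; k++) {
      double old = aux[k];
      double cand = old + R::norm_rand() * a_aux.step(k);
      double lp0 = lp_aux(k, old), ll0 = cur_ll;
      aux[k] = cand;
      double ll1 = ll_all();
      bool acc = std::log(R::unif_rand()) < (ll1 - ll0 + lp_aux(k, cand) - lp0);
      if (acc) cur_ll = ll1; else aux[k] = old;
      a_aux.tune(k, acc, warm);
    }

    // random effects: propose per group, local likelihood only
    auto update_re = [&](std::vector<double> &u, double lsd, Adapt &ad,
                         std::vector<std::vector<int>> &rows, bool slope,
                         const char which) {
      int J = u.size();
      double sdv = std::exp(lsd);
      for (int j = 0; j < J; j++) {
        if (rows[j].empty()) continue;
        double d = R::norm_rand() * ad.step(j);
        double ll0 = ll_rows(rows[j]);
        for (int i : rows[j]) eta[i] += slope ? tvec[i] * d : d;
        double ll1 = ll_rows(rows[j]);
        double dpr = R::dnorm(u[j] + d, 0.0, sdv, 1) -
                     R::dnorm(u[j], 0.0, sdv, 1);
        bool acc = std::log(R::unif_rand()) < (ll1 - ll0 + dpr);
        if (acc) {
          u[j] += d;
          cur_ll += (ll1 - ll0);
        } else {
          for (int i : rows[j]) eta[i] -= slope ? tvec[i] * d : d;
        }
        ad.tune(j, acc, warm);
      }
      (void)which;
    };
    if (has_u1) update_re(u1, ls_u1, a_u1, rows1, false, '1');
    if (has_u1s) update_re(u1s, ls_u1s, a_u1s, rows1, true, 's');
    if (has_u2) update_re(u2, ls_u2, a_u2, rows2, false, '2');
    if (has_u2s) update_re(u2s, ls_u2s, a_u2s, rows2, true, 't');

    // RE standard deviations (likelihood unchanged, prior on u only)
    auto update_sd = [&](double &lsd, const std::vector<double> &u, int slot) {
      double cand = lsd + R::norm_rand() * a_sd.step(slot);
      double lp0 = lp_logsd(lsd), lp1 = lp_logsd(cand);
      double s0 = std::exp(lsd), s1 = std::exp(cand);
      for (double v : u) {
        lp0 += R::dnorm(v, 0.0, s0, 1);
        lp1 += R::dnorm(v, 0.0, s1, 1);
      }
      bool acc = std::log(R::unif_rand()) < (lp1 - lp0);
      if (acc) lsd = cand;
      a_sd.tune(slot, acc, warm);
    };
    if (has_u1) update_sd(ls_u1, u1, 0);
    if (has_u1s) update_sd(ls_u1s, u1s, 1);
    if (has_u2) update_sd(ls_u2, u2, 2);
    if (has_u2s) update_sd(ls_u2s, u2s, 3);

    if (!warm && ((it - n_warmup) % thin == 0) && kept < n_keep) {
      int col = 0;
      for (int j = 0; j < p; j++) draws(kept, col++) = beta[j];
      for (int k = 0; k < n_aux; k++) draws(kept, col++) = aux[k];
      if (has_u1) draws(kept, col++) = std::exp(ls_u1);
      if (has_u1s) draws(kept, col++) = std::exp(ls_u1s);
      if (has_u2) draws(kept, col++) = std::exp(ls_u2);
      if (has_u2s) draws(kept, col++) = std::exp(ls_u2s);
      for (int j = 0; j < J1; j++) {
        u1_mean[j] += u1[j];
        u1s_mean[j] += u1s[j];
      }
      for (int j = 0; j < J2; j++) {
        u2_mean[j] += u2[j];
        u2s_mean[j] += u2s[j];
      }
      kept++;
    }
  }
  if (kept > 0) {
    for (int j = 0; j < J1; j++) { u1_mean[j] /= kept; u1s_mean[j] /= kept; }
    for (int j = 0; j < J2; j++) { u2_mean[j] /= kept; u2s_mean[j] /= kept; }
  }
  return List::create(
      _["draws"] = draws, _["u1_mean"] = u1_mean, _["u1s_mean"] = u1s_mean,
      _["u2_mean"] = u2_mean, _["u2s_mean"] = u2s_mean,
      _["accept_beta"] = prop_beta > 0 ? acc_beta / prop_beta : NA_REAL);
}
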
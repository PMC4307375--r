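#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Link codes: 0 = odds, 1 = logit, 2 = cloglog.
//
// The sampler works with log(phi_X) and log(1 - phi_X) directly so that
// extreme linear predictors stay finite; a predictor with no valid inverse
// (odds link, eta <= 0, or cloglog underflow to phi_X == 0/1) yields
// log-likelihood -Inf, i.e. the proposal is rejected, keeping the posterior
// supported on valid states without clipping.

static inline double log1pexp_c(double x) {
  // log(1 + exp(x)), stable
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline bool inv_link_logs(double eta, int link, double &lp, double &lq) {
  switch (link) {
  case 0: // odds: phi = eta / (1 + eta), defined for eta > 0
    if (!(eta > 0.0)) return false;
    lq = -std::log1p(eta);
    lp = std::log(eta) + lq;
    return true;
  case 1: { // logit
    double l = log1pexp_c(-eta);
    lp = -l;
    lq = -eta - l;
    return true;
  }
  default: { // cloglog: phi = 1 - exp(-exp(eta))
    double t = std::exp(eta);
    if (!std::isfinite(t)) return false;     // phi indistinguishable from 1
    lq = -t;
    double phi = -std::expm1(-t);
    if (phi <= 0.0) return false;            // underflow: phi == 0
    lp = std::log(phi);
    return true;
  }
  }
}

static inline double link_from_z(double z, double phi, int link) {
  // link(phi) given the logit-scale state z = logit(phi)
  switch (link) {
  case 0:  return std::exp(z);          // odds
  case 1:  return z;                    // logit: the state itself
  default: return std::log(-std::log1p(-phi));
  }
}

// Endpoint-count log-likelihood term of one trial (binomial kernel, constants
// dropped): XT * log(phi_X) + (X - XT) * log(1 - phi_X); -Inf when invalid.
static inline double x_loglik(double eta, int link, double XT, double X) {
  double lp, lq;
  if (!inv_link_logs(eta, link, lp, lq)) return R_NegInf;
  return XT * lp + (X - XT) * lq;
}

// One Metropolis-within-Gibbs chain for the trial-level association model.
//
//   B_Ti ~ Binomial(B_i, phi_Bi)
//   X_Ti ~ Binomial(X_i, phi_Xi),  g(phi_Xi) = beta0 + beta * g(phi_Bi)
//   beta0 ~ Normal(0, beta0_sd^2), beta ~ Uniform(beta_lo, beta_hi),
//   phi_Bi ~ Beta(aB_i, bB_i)
//
// Updates: random-walk on beta0; a slope move on beta that shifts beta0 so
// the fitted value at the covariate centre gbar stays fixed (decorrelates
// the two, a standard centring trick; the proposal is a linear volume-
// preserving map so the usual MH ratio applies); logit-scale random walks on
// each phi_Bi. Step sizes adapt toward 44% acceptance during burn-in only.
// Uses R's RNG, so results are governed by set.seed().
// [[Rcpp::export(name = ".mcmc_chain_cpp")]]
List mcmc_chain_cpp(NumericVector B, NumericVector BT,
                    NumericVector X, NumericVector XT,
                    int link, double beta0_sd,
                    double beta_lo, double beta_hi,
                    NumericVector aB, NumericVector bB,
                    int n_burnin, int n_iter, int thin,
                    double beta0_init, double beta_init,
                    NumericVector phiB_init) {
  const int N = B.size();
  const bool beta_fixed = (beta_lo == beta_hi);
  const double prec0 = 0.5 / (beta0_sd * beta0_sd);

  // state
  double beta0 = beta0_init, beta = beta_fixed ? beta_lo : beta_init;
  std::vector<double> z(N), phi(N), g(N), bll(N), xll(N), xll_new(N);
  std::vector<double> lphv(N), lqv(N);  // cached log(phi), log(1 - phi)
  // combined Beta-prior + biomarker-binomial exponents (constants dropped):
  // (BT + aB - 1) log phi + (B - BT + bB - 1) log(1 - phi)
  std::vector<double> ea(N), eb(N);
  for (int i = 0; i < N; ++i) {
    ea[i] = BT[i] + aB[i] - 1.0;
    eb[i] = B[i] - BT[i] + bB[i] - 1.0;
    phi[i] = phiB_init[i];
    z[i] = std::log(phi[i]) - std::log1p(-phi[i]);
    g[i] = link_from_z(z[i], phi[i], link);
  }
  double gbar = 0.0;
  for (int i = 0; i < N; ++i) gbar += g[i];
  gbar /= N;

  for (int i = 0; i < N; ++i) {
    lphv[i] = std::log(phi[i]);
    lqv[i] = std::log1p(-phi[i]);
    bll[i] = ea[i] * lphv[i] + eb[i] * lqv[i];
    xll[i] = x_loglik(beta0 + beta * g[i], link, XT[i], X[i]);
  }

  // proposal scales (log-scale adaptation during burn-in)
  double s0 = 0.5, s1 = 0.5;
  std::vector<double> sp(N, 0.8);
  int acc0 = 0, acc1 = 0;
  std::vector<int> accp(N, 0);
  const int batch = 50;
  int batch_n = 0, batch_count = 0;

  const int n_kept = n_iter / thin;
  NumericVector out_beta0(n_kept), out_beta(n_kept);
  NumericMatrix out_phi(n_kept, N);
  int kept = 0;
  long acc0_tot = 0, acc1_tot = 0, prop_tot = 0;

  const int total = n_burnin + n_iter;
  for (int it = 0; it < total; ++it) {
    const bool burn = it < n_burnin;

    // --- beta0 update ---
    {
      double prop = beta0 + s0 * norm_rand();
      double dlp = prec0 * (beta0 * beta0 - prop * prop);
      bool ok = true;
      for (int i = 0; i < N; ++i) {
        xll_new[i] = x_loglik(prop + beta * g[i], link, XT[i], X[i]);
        if (xll_new[i] == R_NegInf) { ok = false; break; }
        dlp += xll_new[i] - xll[i];
      }
      if (ok && std::log(unif_rand()) < dlp) {
        beta0 = prop;
        std::copy(xll_new.begin(), xll_new.end(), xll.begin());
        ++acc0; ++acc0_tot;
      }
    }

    // --- beta update (slope move pivoting at gbar) ---
    if (!beta_fixed) {
      double e = s1 * norm_rand();
      double beta_p = beta + e, beta0_p = beta0 - e * gbar;
      if (beta_p >= beta_lo && beta_p <= beta_hi) {
        double dlp = prec0 * (beta0 * beta0 - beta0_p * beta0_p);
        bool ok = true;
        for (int i = 0; i < N; ++i) {
          xll_new[i] = x_loglik(beta0_p + beta_p * g[i], link, XT[i], X[i]);
          if (xll_new[i] == R_NegInf) { ok = false; break; }
          dlp += xll_new[i] - xll[i];
        }
        if (ok && std::log(unif_rand()) < dlp) {
          beta = beta_p; beta0 = beta0_p;
          std::copy(xll_new.begin(), xll_new.end(), xll.begin());
          ++acc1; ++acc1_tot;
        }
      }
      ++prop_tot;
    }

    // --- per-trial phi_B updates (logit-scale random walk) ---
    for (int i = 0; i < N; ++i) {
      double zp = z[i] + sp[i] * norm_rand();
      double lph = -log1pexp_c(-zp);    // log(phi')
      double lqh = -zp + lph;           // log(1 - phi')
      double php = std::exp(lph);
      if (php <= 0.0 || php >= 1.0) continue; // numerically degenerate
      double gp = link_from_z(zp, php, link);
      double xln = x_loglik(beta0 + beta * gp, link, XT[i], X[i]);
      if (xln == R_NegInf) continue;
      double bln = ea[i] * lph + eb[i] * lqh;
      // Jacobian of the logit reparameterization: log(phi (1 - phi))
      double dlp = (bln + xln + lph + lqh) -
        (bll[i] + xll[i] + lphv[i] + lqv[i]);
      if (std::log(unif_rand()) < dlp) {
        z[i] = zp; phi[i] = php; g[i] = gp; bll[i] = bln; xll[i] = xln;
        lphv[i] = lph; lqv[i] = lqh;
        ++accp[i];
      }
    }

    // --- burn-in adaptation ---
    if (burn && ++batch_n == batch) {
      ++batch_count;
      double delta = std::min(0.1, 1.0 / std::sqrt((double)batch_count));
      s0 *= std::exp(((double)acc0 / batch > 0.44 ? delta : -delta));
      s1 *= std::exp(((double)acc1 / batch > 0.44 ? delta : -delta));
      for (int i = 0; i < N; ++i)
        sp[i] *= std::exp(((double)accp[i] / batch > 0.44 ? delta : -delta));
      acc0 = acc1 = 0;
      std::fill(accp.begin(), accp.end(), 0);
      batch_n = 0;
    }

    // --- storage ---
    if (!burn && ((it - n_burnin + 1) % thin == 0) && kept < n_kept) {
      out_beta0[kept] = beta0;
      out_beta[kept] = beta;
      for (int i = 0; i < N; ++i) out_phi(kept, i) = phi[i];
      ++kept;
    }

    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["beta0"] = out_beta0,
    _["beta"] = out_beta,
    _["phi_b"] = out_phi,
    _["accept_beta0"] = (double)acc0_tot / total,
    _["accept_beta"] = prop_tot > 0 ? (double)acc1_tot / prop_tot : NA_REAL,
    _["step_beta0"] = s0, _["step_beta"] = s1);
}
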
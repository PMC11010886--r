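// Single-site Gibbs samplers for the Bayesian whole-genome regressions.
//
// One routine covers the three priors:
//   model 0 (BayesA): every marker has an effect with its own
//     scaled-inverse-chi-square variance (df v, scale S);
//   model 1 (BayesB): point-mass mixture with null fraction pi; an
//     included marker has its own variance as in BayesA. The indicator is
//     sampled from the marginal likelihood ratio with the effect
//     integrated out.
//   model 2 (BayesC): point-mass mixture with one variance shared by all
//     included markers.
//
// The residual vector e = y - X b - M g is carried through every update.
// All draws use R's RNG, so chains are reproducible from set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double dot_col(const double* col, const double* e, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += col[i] * e[i];
  return s;
}

// [[Rcpp::export]]
List gibbs_sampler_cpp(NumericVector y, NumericMatrix X, NumericMatrix M,
                       int model, int n_iter, int burn_in, int thin,
                       double v, double S, double pi_null,
                       double ve, double Se,
                       bool fix_sigma_e, double sigma_e_fix,
                       bool fix_sigma_m, double sigma_m_fix) {
  const int n = y.size();
  const int p = X.ncol();
  const int m = M.ncol();
  const double VAR_FLOOR = 1e-12;

  std::vector<double> e(n), b(p, 0.0), g(m, 0.0);
  std::vector<double> xtx(p), ctc(m);
  std::vector<double> sigma_gi(m);
  std::vector<int> delta(m, 1);

  for (int i = 0; i < n; ++i) e[i] = y[i];
  for (int j = 0; j < p; ++j) {
    const double* col = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += col[i] * col[i];
    xtx[j] = s;
  }
  for (int k = 0; k < m; ++k) {
    const double* col = &M(0, k);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += col[i] * col[i];
    ctc[k] = s;
  }

  double prior_var = (v > 2.0) ? S * v / (v - 2.0) : S;
  if (prior_var < VAR_FLOOR) prior_var = VAR_FLOOR;
  for (int k = 0; k < m; ++k) sigma_gi[k] = prior_var;
  double sigma_m = prior_var;
  double vy = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) my += y[i];
  my /= n;
  for (int i = 0; i < n; ++i) vy += (y[i] - my) * (y[i] - my);
  vy = (n > 1) ? vy / (n - 1) : 1.0;
  double sigma_e = fix_sigma_e ? sigma_e_fix : std::max(vy / 2.0, VAR_FLOOR);
  if (fix_sigma_m) sigma_m = sigma_m_fix;

  const double log_prior_odds =
      (pi_null > 0.0) ? std::log((1.0 - pi_null) / pi_null) : 0.0;

  const int n_kept_max = (n_iter - burn_in + thin - 1) / thin;
  std::vector<double> g_sum(m, 0.0), b_sum(p, 0.0), delta_sum(m, 0.0);
  std::vector<double> sigma_e_chain;
  sigma_e_chain.reserve(n_kept_max);
  double sigma_m_sum = 0.0;
  int n_kept = 0;

  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    // fixed effects, flat prior
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) continue;
      const double* col = &X(0, j);
      double r = dot_col(col, e.data(), n) + xtx[j] * b[j];
      double mean = r / xtx[j];
      double bn = ::Rf_rnorm(mean, std::sqrt(sigma_e / xtx[j]));
      double diff = b[j] - bn;
      for (int i = 0; i < n; ++i) e[i] += col[i] * diff;
      b[j] = bn;
    }

    // marker effects
    double sum_g2_incl = 0.0;
    int n_incl = 0;
    for (int k = 0; k < m; ++k) {
      const double* col = &M(0, k);
      const double c = ctc[k];
      double s2 = (model == 2) ? sigma_m : sigma_gi[k];
      if (s2 < VAR_FLOOR) s2 = VAR_FLOOR;
      double r = dot_col(col, e.data(), n) + c * g[k];
      double gn = 0.0;
      int dn = 1;

      if (model == 0 || pi_null <= 0.0) {
        if (c > 0.0) {
          double lambda = sigma_e / s2;
          double denom = c + lambda;
          gn = ::Rf_rnorm(r / denom, std::sqrt(sigma_e / denom));
        } else {
          gn = ::Rf_rnorm(0.0, std::sqrt(s2));  // prior draw, no data
        }
      } else {
        // marginal likelihood ratio for inclusion (effect integrated out)
        double logit;
        if (c > 0.0) {
          double lambda = sigma_e / s2;
          double log_lr = 0.5 * (std::log(lambda / (c + lambda)) +
                                 r * r / (sigma_e * (c + lambda)));
          logit = log_prior_odds + log_lr;
        } else {
          logit = log_prior_odds;
        }
        double p1 = 1.0 / (1.0 + std::exp(-logit));
        dn = (::Rf_runif(0.0, 1.0) < p1) ? 1 : 0;
        if (dn == 1) {
          if (c > 0.0) {
            double lambda = sigma_e / s2;
            double denom = c + lambda;
            gn = ::Rf_rnorm(r / denom, std::sqrt(sigma_e / denom));
          } else {
            gn = ::Rf_rnorm(0.0, std::sqrt(s2));
          }
        }
      }

      double diff = g[k] - gn;
      if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] += col[i] * diff;
      g[k] = gn;
      delta[k] = dn;

      if (model == 0) {
        sigma_gi[k] = std::max((v * S + gn * gn) / ::Rf_rchisq(v + 1.0),
                               VAR_FLOOR);
      } else if (model == 1) {
        if (dn == 1) {
          sigma_gi[k] = std::max((v * S + gn * gn) / ::Rf_rchisq(v + 1.0),
                                 VAR_FLOOR);
        } else {
          sigma_gi[k] = std::max(v * S / ::Rf_rchisq(v), VAR_FLOOR);
        }
      } else {
        if (dn == 1) { sum_g2_incl += gn * gn; ++n_incl; }
      }
    }

    if (model == 2 && !fix_sigma_m) {
      sigma_m = std::max((v * S + sum_g2_incl) / ::Rf_rchisq(v + n_incl),
                         VAR_FLOOR);
    }

    if (!fix_sigma_e) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma_e = std::max((sse + ve * Se) / ::Rf_rchisq((double)n + ve),
                         VAR_FLOOR);
    }

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      for (int k = 0; k < m; ++k) {
        g_sum[k] += g[k];
        delta_sum[k] += delta[k];
      }
      for (int j = 0; j < p; ++j) b_sum[j] += b[j];
      sigma_e_chain.push_back(sigma_e);
      sigma_m_sum += (model == 2) ? sigma_m : 0.0;
      ++n_kept;
    }
  }

  NumericVector g_mean(m), incl_freq(m), b_mean(p);
  for (int k = 0; k < m; ++k) {
    g_mean[k] = g_sum[k] / n_kept;
    incl_freq[k] = delta_sum[k] / n_kept;
  }
  for (int j = 0; j < p; ++j) b_mean[j] = b_sum[j] / n_kept;
  NumericVector se_chain(sigma_e_chain.begin(), sigma_e_chain.end());
  double se_mean = 0.0;
  for (double x : sigma_e_chain) se_mean += x;
  se_mean /= n_kept;

  return List::create(
      Named("g_mean") = g_mean, Named("b_mean") = b_mean,
      Named("incl_freq") = incl_freq,
      Named("sigma_e_chain") = se_chain,
      Named("sigma_e_mean") = se_mean,
      Named("sigma_m_mean") =
          (model == 2) ? sigma_m_sum / n_kept : NA_REAL,
      Named("n_kept") = n_kept);
}
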
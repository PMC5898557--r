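#include <Rcpp.h>
using namespace Rcpp;

// Stable log(1 + exp(x)).
static inline double splus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Unnormalised log posterior on binomial sufficient statistics.
// kind: 1 fractional (theta_A, theta_B, f)
//       2 conventional (theta_A, theta_B, theta_AB)
//       3 full additivity (theta_A, theta_B)
// Arms ordered A, B, AB in n / y.
static double logpost(const double* par, int kind,
                      const double* n, const double* y,
                      double pm_f, double pv_f, double sd_theta) {
  double tA = par[0], tB = par[1], tAB, lp = 0.0;
  double v_theta = sd_theta * sd_theta;
  if (kind == 1) {
    double f = par[2];
    tAB = std::max(tA, tB) + f * std::min(tA, tB);
    double d = f - pm_f;
    lp -= 0.5 * d * d / pv_f;
  } else if (kind == 2) {
    tAB = par[2];
    lp -= 0.5 * tAB * tAB / v_theta;
  } else {
    tAB = tA + tB;
  }
  lp -= 0.5 * (tA * tA + tB * tB) / v_theta;
  lp += y[0] * tA  - n[0] * splus(tA);
  lp += y[1] * tB  - n[1] * splus(tB);
  lp += y[2] * tAB - n[2] * splus(tAB);
  return lp;
}

// Adaptive random-walk Metropolis. Joint Gaussian proposal with
// per-coordinate step sizes; a single global scale is tuned during warmup
// (blocks of 50 iterations, targeting ~30% acceptance) and frozen afterwards.
// Uses R's RNG, so draws are reproducible via set.seed() on the R side.
// [[Rcpp::export]]
List rwm_sample(int kind, NumericVector n, NumericVector y,
                double prior_mean_f, double prior_var_f, double prior_sd_theta,
                NumericVector init, NumericVector step,
                int warmup, int n_keep, int thin) {
  const int d = (kind == 3) ? 2 : 3;
  if (init.size() != d || step.size() != d)
    stop("init/step dimension does not match the model kind");

  std::vector<double> cur(init.begin(), init.end());
  std::vector<double> prop(d);
  std::vector<double> s(step.begin(), step.end());
  double scale = 1.0;
  const double target = 0.30;

  double lp = logpost(cur.data(), kind, n.begin(), y.begin(),
                      prior_mean_f, prior_var_f, prior_sd_theta);

  int block_acc = 0, block_n = 0;
  for (int it = 0; it < warmup; ++it) {
    for (int j = 0; j < d; ++j) prop[j] = cur[j] + scale * s[j] * R::norm_rand();
    double lp_new = logpost(prop.data(), kind, n.begin(), y.begin(),
                            prior_mean_f, prior_var_f, prior_sd_theta);
    if (std::log(R::unif_rand()) < lp_new - lp) {
      cur = prop; lp = lp_new; ++block_acc;
    }
    if (++block_n == 50) {
      double acc = (double)block_acc / block_n;
      double fac = std::exp(acc - target);
      if (fac < 0.5) fac = 0.5;
      if (fac > 2.0) fac = 2.0;
      scale *= fac;
      block_acc = 0; block_n = 0;
    }
  }

  NumericMatrix draws(n_keep, d);
  long accepted = 0, total = 0;
  for (int k = 0; k < n_keep; ++k) {
    for (int t = 0; t < thin; ++t) {
      for (int j = 0; j < d; ++j) prop[j] = cur[j] + scale * s[j] * R::norm_rand();
      double lp_new = logpost(prop.data(), kind, n.begin(), y.begin(),
                              prior_mean_f, prior_var_f, prior_sd_theta);
      ++total;
      if (std::log(R::unif_rand()) < lp_new - lp) {
        cur = prop; lp = lp_new; ++accepted;
      }
    }
    for (int j = 0; j < d; ++j) draws(k, j) = cur[j];
  }

  return List::create(
    _["draws"] = draws,
    _["acceptance_rate"] = total > 0 ? (double)accepted / total : NA_REAL,
    _["scale"] = scale
  );
}
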
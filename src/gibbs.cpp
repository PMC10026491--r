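#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Standard normal truncated to [a, Inf): naive rejection for moderate a,
// Robert (1995) exponential rejection for far-tail truncation.
static inline double rtnorm_std_lower(double a) {
  if (a < 0.45) {
    double z;
    do { z = norm_rand(); } while (z < a);
    return z;
  }
  const double lambda = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double z = a + exp_rand() / lambda;
    double d = z - lambda;
    if (std::log(unif_rand()) <= -0.5 * d * d) return z;
  }
}

static inline double rtnorm_lower(double m, double s, double lo) {
  return m + s * rtnorm_std_lower((lo - m) / s);
}

static inline double rtnorm_upper(double m, double s, double hi) {
  return m - s * rtnorm_std_lower((m - hi) / s);
}

// X ~ IG(shape, scale) <=> 1/X ~ Gamma(shape, rate = scale)
static inline double rinvgamma(double shape, double scale) {
  double g = R::rgamma(shape, 1.0 / scale);
  if (g < 1e-300) g = 1e-300;
  double v = 1.0 / g;
  return (v < 1e-12) ? 1e-12 : v;
}

// Gibbs sampler for the two-subset hierarchical model on per-subgroup
// sufficient statistics (n, ybar) with known outcome variance sigma2:
//   ybar_i | theta_i ~ N(theta_i, sigma2 / n_i)
//   theta_i ~ N(theta_hi, var_hi) if high[i], else N(theta_lo, var_lo)
//   theta_hi ~ N(m_hi, v_hi), theta_lo ~ N(m_lo, v_lo), theta_hi > theta_lo
//   var_hi ~ IG(a_hi, b_hi), var_lo ~ IG(a_lo, b_lo)
// The ordering constraint is enforced by truncated-normal full conditionals.
// [[Rcpp::export(name = ".gibbs_two_subset")]]
List gibbs_two_subset(NumericVector ybar, NumericVector n, LogicalVector high,
                      double sigma2,
                      double m_hi, double v_hi, double m_lo, double v_lo,
                      double a_hi, double b_hi, double a_lo, double b_lo,
                      int n_iter, int n_burn, int thin, bool constrain) {
  const int m = ybar.size();
  int n_hi = 0, n_lo = 0;
  for (int i = 0; i < m; ++i) (high[i] ? n_hi : n_lo)++;

  std::vector<double> theta(m);
  double sum_hi = 0.0, sum_lo = 0.0;
  for (int i = 0; i < m; ++i) {
    theta[i] = (n[i] > 0) ? ybar[i] : (high[i] ? m_hi : m_lo);
    (high[i] ? sum_hi : sum_lo) += theta[i];
  }
  double theta_hi = n_hi ? sum_hi / n_hi : m_hi;
  double theta_lo = n_lo ? sum_lo / n_lo : m_lo;
  if (theta_hi <= theta_lo) theta_hi = theta_lo + 1.0;
  double var_hi = 1.0, var_lo = 1.0;

  const int n_keep = (n_iter - n_burn + thin - 1) / thin;
  NumericMatrix theta_draws(n_keep, m);
  NumericVector hi_draws(n_keep), lo_draws(n_keep);
  NumericVector vhi_draws(n_keep), vlo_draws(n_keep);

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // subgroup effects
    sum_hi = 0.0; sum_lo = 0.0;
    for (int i = 0; i < m; ++i) {
      const double mu = high[i] ? theta_hi : theta_lo;
      const double v = high[i] ? var_hi : var_lo;
      double vpost, mpost;
      if (n[i] > 0) {
        const double prec = n[i] / sigma2 + 1.0 / v;
        vpost = 1.0 / prec;
        mpost = vpost * (n[i] * ybar[i] / sigma2 + mu / v);
      } else {
        vpost = v; mpost = mu;  // no likelihood contribution
      }
      theta[i] = mpost + std::sqrt(vpost) * norm_rand();
      (high[i] ? sum_hi : sum_lo) += theta[i];
    }
    // subset means, constrained theta_hi > theta_lo when requested
    {
      const double prec = 1.0 / v_hi + n_hi / var_hi;
      const double mean = (m_hi / v_hi + sum_hi / var_hi) / prec;
      const double s = std::sqrt(1.0 / prec);
      theta_hi = constrain ? rtnorm_lower(mean, s, theta_lo)
                           : mean + s * norm_rand();
    }
    {
      const double prec = 1.0 / v_lo + n_lo / var_lo;
      const double mean = (m_lo / v_lo + sum_lo / var_lo) / prec;
      const double s = std::sqrt(1.0 / prec);
      theta_lo = constrain ? rtnorm_upper(mean, s, theta_hi)
                           : mean + s * norm_rand();
    }
    // shrinkage variances
    double ss_hi = 0.0, ss_lo = 0.0;
    for (int i = 0; i < m; ++i) {
      const double d = theta[i] - (high[i] ? theta_hi : theta_lo);
      (high[i] ? ss_hi : ss_lo) += d * d;
    }
    var_hi = rinvgamma(a_hi + 0.5 * n_hi, b_hi + 0.5 * ss_hi);
    var_lo = rinvgamma(a_lo + 0.5 * n_lo, b_lo + 0.5 * ss_lo);

    if (it >= n_burn && (it - n_burn) % thin == 0) {
      for (int i = 0; i < m; ++i) theta_draws(kept, i) = theta[i];
      hi_draws[kept] = theta_hi; lo_draws[kept] = theta_lo;
      vhi_draws[kept] = var_hi; vlo_draws[kept] = var_lo;
      ++kept;
    }
  }
  return List::create(_["theta"] = theta_draws,
                      _["theta_high"] = hi_draws, _["theta_low"] = lo_draws,
                      _["var_high"] = vhi_draws, _["var_low"] = vlo_draws);
}

// Exchangeable (single-subset) hierarchical model: all subgroup effects
// drawn from one common N(theta_pool, var_pool).
// [[Rcpp::export(name = ".gibbs_exchangeable")]]
List gibbs_exchangeable(NumericVector ybar, NumericVector n, double sigma2,
                        double m0, double v0, double a, double b,
                        int n_iter, int n_burn, int thin) {
  const int m = ybar.size();
  std::vector<double> theta(m);
  double sum = 0.0;
  for (int i = 0; i < m; ++i) {
    theta[i] = (n[i] > 0) ? ybar[i] : m0;
    sum += theta[i];
  }
  double theta_pool = sum / m, var_pool = 1.0;

  const int n_keep = (n_iter - n_burn + thin - 1) / thin;
  NumericMatrix theta_draws(n_keep, m);
  NumericVector pool_draws(n_keep), vpool_draws(n_keep);

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    sum = 0.0;
    for (int i = 0; i < m; ++i) {
      double vpost, mpost;
      if (n[i] > 0) {
        const double prec = n[i] / sigma2 + 1.0 / var_pool;
        vpost = 1.0 / prec;
        mpost = vpost * (n[i] * ybar[i] / sigma2 + theta_pool / var_pool);
      } else {
        vpost = var_pool; mpost = theta_pool;
      }
      theta[i] = mpost + std::sqrt(vpost) * norm_rand();
      sum += theta[i];
    }
    const double prec = 1.0 / v0 + m / var_pool;
    const double mean = (m0 / v0 + sum / var_pool) / prec;
    theta_pool = mean + std::sqrt(1.0 / prec) * norm_rand();
    double ss = 0.0;
    for (int i = 0; i < m; ++i) {
      const double d = theta[i] - theta_pool;
      ss += d * d;
    }
    var_pool = rinvgamma(a + 0.5 * m, b + 0.5 * ss);

    if (it >= n_burn && (it - n_burn) % thin == 0) {
      for (int i = 0; i < m; ++i) theta_draws(kept, i) = theta[i];
      pool_draws[kept] = theta_pool; vpool_draws[kept] = var_pool;
      ++kept;
    }
  }
  return List::create(_["theta"] = theta_draws,
                      _["theta_pool"] = pool_draws, _["var_pool"] = vpool_draws);
}
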
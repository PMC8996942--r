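// Single-site Gibbs samplers for whole-genome regression
// y_i = mu + sum_j W_ij g_j + e_i,  e_i ~ N(0, sigma2_e / w_i)
//
// Model codes: 0 = BRR, 1 = BayesA, 2 = BayesB, 3 = BayesC, 4 = Bayesian
// Lasso. Residual updating keeps each sweep O(n * p). R's RNG is used so
// set.seed() governs reproducibility.

#include <Rcpp.h>
using namespace Rcpp;

// scaled-inverse-chi-square draw: (ssq + df0 * S0) / chisq(df0 + n)
static inline double rscinvchisq(double df, double scale_sum) {
  return scale_sum / R::rchisq(df);
}

// inverse-Gaussian via Michael-Schucany-Haas transformation
static inline double rinvgauss(double mu, double lambda) {
  double z = R::rnorm(0.0, 1.0);
  double y = z * z;
  double x = mu + 0.5 * mu * mu * y / lambda -
    0.5 * (mu / lambda) * std::sqrt(4.0 * mu * lambda * y +
                                    mu * mu * y * y);
  if (R::runif(0.0, 1.0) <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export(name = ".gibbs_wgr")]]
List gibbs_wgr(NumericMatrix W, NumericVector y, NumericVector w,
               int model, int niter, int burnin, int thin,
               double df0, double Sg, double dfe, double Se,
               double pi0, double pi_counts,
               double bl_shape, double bl_rate,
               bool fix_var_g, double var_g_value,
               bool fix_var_e, double var_e_value,
               bool update_pi) {
  const int n = W.nrow(), p = W.ncol();
  if (y.size() != n || w.size() != n)
    stop("length of y/weights does not match rows of W");

  // sufficient statistics of the columns under the record weights
  std::vector<double> wtw(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += w[i] * W(i, j) * W(i, j);
    wtw[j] = s;
  }
  double sw = 0.0;
  for (int i = 0; i < n; ++i) sw += w[i];

  // state
  double mu = 0.0;
  std::vector<double> g(p, 0.0), sig2j(p, Sg), tau2(p, 1.0);
  std::vector<int> delta(p, 1);
  double sig2g = fix_var_g ? var_g_value : Sg;
  double sig2e = fix_var_e ? var_e_value : Se;
  double pi = pi0;
  double lambda2 = (bl_rate > 0.0) ? bl_shape / bl_rate : 1.0;
  const bool pointmass = (model == 2 || model == 3);
  if (!pointmass) std::fill(delta.begin(), delta.end(), 1);

  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];

  // accumulators
  std::vector<double> g_sum(p, 0.0), pip_sum(p, 0.0);
  int nkeep = (niter - burnin) / thin;
  NumericVector mu_s(nkeep), vg_s(nkeep), ve_s(nkeep), pi_s(nkeep);
  int kept = 0;

  RNGScope scope;
  for (int it = 1; it <= niter; ++it) {
    // intercept
    {
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += w[i] * (e[i] + mu);
      double cinv = sig2e / sw;
      double mu_new = R::rnorm(rhs / sw, std::sqrt(cinv));
      for (int i = 0; i < n; ++i) e[i] -= (mu_new - mu);
      mu = mu_new;
    }
    int m_in = 0;
    double ssq_in = 0.0;     // sum g^2 over included (common-variance models)
    double ssq_tau = 0.0;    // BL: sum g_j^2 / tau_j^2
    for (int j = 0; j < p; ++j) {
      double vj;             // prior variance of g_j given the hierarchy
      switch (model) {
      case 0: vj = sig2g; break;
      case 1: vj = sig2j[j]; break;
      case 2: vj = sig2j[j]; break;
      case 3: vj = sig2g; break;
      default: vj = tau2[j] * sig2e; break;
      }
      double gj_cur = (delta[j] ? g[j] : 0.0);
      // r = w-weighted W_j' (e + W_j g_j)
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += w[i] * W(i, j) * e[i];
      r += wtw[j] * gj_cur;
      double C = wtw[j] / sig2e + 1.0 / vj;
      double rhs = r / sig2e;
      bool include = true;
      if (pointmass) {
        double logodds = std::log(pi) - std::log(1.0 - pi) +
          0.5 * (-std::log(vj) - std::log(C)) + 0.5 * rhs * rhs / C;
        double pr = 1.0 / (1.0 + std::exp(-logodds));
        include = (R::runif(0.0, 1.0) < pr);
      }
      double gj_new = 0.0;
      if (include) {
        gj_new = R::rnorm(rhs / C, std::sqrt(1.0 / C));
        ++m_in;
      }
      if (gj_new != gj_cur) {
        double d = gj_new - gj_cur;
        for (int i = 0; i < n; ++i) e[i] -= W(i, j) * d;
      }
      g[j] = gj_new;
      delta[j] = include ? 1 : 0;
      if (include) ssq_in += gj_new * gj_new;
      if (model == 4 && tau2[j] > 0.0) ssq_tau += gj_new * gj_new / tau2[j];

      // per-marker variance hierarchies
      if (model == 1 || model == 2)
        sig2j[j] = rscinvchisq(df0 + (include ? 1.0 : 0.0),
                               gj_new * gj_new + df0 * Sg);
      if (model == 4) {
        double g2 = gj_new * gj_new;
        if (g2 < 1e-12) g2 = 1e-12;
        double itau = rinvgauss(std::sqrt(lambda2 * sig2e / g2), lambda2);
        if (itau < 1e-10) itau = 1e-10;
        tau2[j] = 1.0 / itau;
      }
    }
    // common marker variance
    if (!fix_var_g) {
      if (model == 0)
        sig2g = rscinvchisq(df0 + p, ssq_in + df0 * Sg);
      else if (model == 3)
        sig2g = rscinvchisq(df0 + m_in, ssq_in + df0 * Sg);
    }
    if (pointmass && update_pi)
      pi = R::rbeta(m_in + pi_counts * pi0,
                    (p - m_in) + pi_counts * (1.0 - pi0));
    if (model == 4) {
      double sum_tau2 = 0.0;
      for (int j = 0; j < p; ++j) sum_tau2 += tau2[j];
      lambda2 = R::rgamma(bl_shape + p, 1.0 / (bl_rate + 0.5 * sum_tau2));
    }
    // residual variance
    if (!fix_var_e) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += w[i] * e[i] * e[i];
      if (model == 4) {
        // g_j | tau_j^2, sig2e ~ N(0, tau_j^2 sig2e): contributes too
        double st = 0.0;
        for (int j = 0; j < p; ++j) st += g[j] * g[j] / tau2[j];
        sig2e = rscinvchisq(n + p + dfe, sse + st + dfe * Se);
      } else {
        sig2e = rscinvchisq(n + dfe, sse + dfe * Se);
      }
    }
    if (!R_FINITE(sig2e) || sig2e > 1e12 ||
        (!fix_var_g && (model == 0 || model == 3) && sig2g > 1e12))
      stop("divergent variance draw at iteration %d", it);

    if (it > burnin && (it - burnin) % thin == 0 && kept < nkeep) {
      for (int j = 0; j < p; ++j) {
        g_sum[j] += g[j];
        pip_sum[j] += delta[j];
      }
      double vg_now;
      switch (model) {
      case 0: case 3: vg_now = sig2g; break;
      case 1: case 2: {
        double s = 0.0;
        for (int j = 0; j < p; ++j) s += sig2j[j];
        vg_now = s / p; break;
      }
      default: {
        double s = 0.0;
        for (int j = 0; j < p; ++j) s += tau2[j];
        vg_now = sig2e * s / p; break;
      }
      }
      mu_s[kept] = mu; vg_s[kept] = vg_now; ve_s[kept] = sig2e;
      pi_s[kept] = pi;
      ++kept;
    }
  }

  NumericVector g_mean(p), pip(p);
  for (int j = 0; j < p; ++j) {
    g_mean[j] = g_sum[j] / kept;
    pip[j] = pip_sum[j] / kept;
  }
  return List::create(_["g_mean"] = g_mean,
                      _["pip"] = pip,
                      _["mu_samples"] = mu_s,
                      _["var_g_samples"] = vg_s,
                      _["var_e_samples"] = ve_s,
                      _["pi_samples"] = pi_s,
                      _["n_kept"] = kept);
}
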
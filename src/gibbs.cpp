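#include <Rcpp.h>
using namespace Rcpp;

// Draw from an inverse-Gaussian(mu, lambda) by the transformation method
// (Michael, Schucany & Haas 1976).
static double rinvgauss(double mu, double lambda) {
  double nu = norm_rand();
  double z = nu * nu;
  double x = mu + mu * mu * z / (2.0 * lambda) -
             mu / (2.0 * lambda) *
                 std::sqrt(4.0 * mu * lambda * z + mu * mu * z * z);
  if (x <= 0.0 || !R_finite(x)) x = 1e-12;
  double u = unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// scaled-inverse-chi-square draw: (ss + S0) / chisq(df)
static double rscinv(double ss, double S0, double df) {
  double c = R::rchisq(df);
  if (c <= 0.0) c = 1e-12;
  return (ss + S0) / c;
}

// Gibbs sampler for y = mu + Z theta + e under five shrinkage priors.
// family: 0 BRR, 1 BayesA, 2 BayesB, 3 BayesC, 4 BL.
// Fixed hyperparameters (NA = estimate) support the conjugate diagnostic
// mode in which every family collapses to the Bayesian-ridge conditional.
// [[Rcpp::export]]
List gibbs_shrinkage_cpp(NumericVector y, NumericMatrix Z, int family,
                         int n_iter, int burn_in, int thin,
                         double df_e, double S_e, double df_b, double S_b,
                         double pi_a, double pi_b,
                         double lambda_shape, double lambda_rate,
                         double fix_var_e, double fix_var_b, double fix_pi,
                         double fix_lambda2) {
  const int n = y.size();
  const int p = Z.ncol();
  const bool ve_fixed = R_finite(fix_var_e);
  const bool vb_fixed = R_finite(fix_var_b);
  const bool pi_fixed = R_finite(fix_pi);
  const bool l2_fixed = R_finite(fix_lambda2);

  // column sums of squares
  std::vector<double> zsq(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    zsq[j] = s;
  }

  // state
  double mu = mean(y);
  std::vector<double> theta(p, 0.0), e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double var_e = ve_fixed ? fix_var_e : std::max(S_e / (df_e + 2.0), 1e-8);
  double var_b = vb_fixed ? fix_var_b : std::max(S_b / (df_b + 2.0), 1e-8);
  std::vector<double> var_j(p, var_b);   // BayesA / BayesB
  std::vector<double> tau2(p, 1.0);      // BL
  std::vector<int> delta(p, 1);          // BayesB / BayesC inclusion
  double pi = pi_fixed ? fix_pi : pi_a / (pi_a + pi_b);
  double lambda2 = l2_fixed ? fix_lambda2
                            : std::max(lambda_shape / lambda_rate, 1e-8);
  if (family == 4 && vb_fixed) {
    // conjugate diagnostic mode: freeze the scale mixture at a point mass
    for (int j = 0; j < p; ++j) tau2[j] = fix_var_b / var_e;
  }

  const int n_save = (n_iter - burn_in) / thin;
  NumericMatrix out_theta(n_save, p);
  NumericVector out_mu(n_save), out_var_e(n_save), out_var_b(n_save),
      out_pi(n_save), out_lambda2(n_save);
  NumericVector delta_mean(p), var_j_mean(p);
  int saved = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // intercept (flat prior)
    {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += e[i] + mu;
      double mbar = s / n;
      double mu_new = mbar + norm_rand() * std::sqrt(var_e / n);
      double d = mu_new - mu;
      for (int i = 0; i < n; ++i) e[i] -= d;
      mu = mu_new;
    }

    // coefficients, fixed column order
    int n_in = 0;
    for (int j = 0; j < p; ++j) {
      double zje = 0.0;
      for (int i = 0; i < n; ++i) zje += Z(i, j) * e[i];
      double rhs = (zje + zsq[j] * theta[j]) / var_e;  // Z_j'(y - mu - Z_-j theta_-j)/var_e
      double prior_var;
      switch (family) {
        case 0: case 3: prior_var = var_b; break;
        case 1: case 2: prior_var = var_j[j]; break;
        default: prior_var = tau2[j] * var_e; break;  // BL
      }
      if (prior_var < 1e-12) prior_var = 1e-12;
      double lhs = zsq[j] / var_e + 1.0 / prior_var;
      double theta_new;
      if (family == 2 || family == 3) {
        // spike-and-slab: marginal Bayes factor for inclusion
        double logBF = 0.5 * (std::log(1.0 / prior_var) - std::log(lhs)) +
                       0.5 * rhs * rhs / lhs;
        double logodds = std::log(pi / (1.0 - pi + 1e-300)) + logBF;
        double prob = 1.0 / (1.0 + std::exp(-logodds));
        if (unif_rand() < prob) {
          delta[j] = 1;
          ++n_in;
          theta_new = rhs / lhs + norm_rand() / std::sqrt(lhs);
        } else {
          delta[j] = 0;
          theta_new = 0.0;
        }
      } else {
        theta_new = rhs / lhs + norm_rand() / std::sqrt(lhs);
      }
      double d = theta_new - theta[j];
      if (d != 0.0) for (int i = 0; i < n; ++i) e[i] -= Z(i, j) * d;
      theta[j] = theta_new;
    }

    // variance hierarchy
    if (family == 0) {                         // BRR
      if (!vb_fixed) {
        double ss = 0.0;
        for (int j = 0; j < p; ++j) ss += theta[j] * theta[j];
        var_b = rscinv(ss, S_b, p + df_b);
      }
    } else if (family == 1 || family == 2) {   // BayesA / BayesB
      if (!vb_fixed) {
        for (int j = 0; j < p; ++j)
          var_j[j] = rscinv(theta[j] * theta[j], S_b, 1.0 + df_b);
      }
    } else if (family == 3) {                  // BayesC
      if (!vb_fixed) {
        double ss = 0.0;
        int k = 0;
        for (int j = 0; j < p; ++j)
          if (delta[j]) { ss += theta[j] * theta[j]; ++k; }
        var_b = rscinv(ss, S_b, k + df_b);
      }
    } else {                                   // Bayesian lasso
      if (!vb_fixed) {
        double sum_tau2 = 0.0;
        for (int j = 0; j < p; ++j) {
          double t2 = theta[j] * theta[j];
          if (t2 < 1e-12) t2 = 1e-12;
          double mu_ig = std::sqrt(lambda2 * var_e / t2);
          if (mu_ig > 1e8) mu_ig = 1e8;
          double inv_tau2 = rinvgauss(mu_ig, lambda2);
          tau2[j] = 1.0 / std::max(inv_tau2, 1e-12);
          sum_tau2 += tau2[j];
        }
        if (!l2_fixed) {
          // lambda^2 ~ Gamma(shape, rate); conditional Gamma(shape + p, rate + sum tau2 / 2)
          lambda2 = R::rgamma(lambda_shape + p,
                              1.0 / (lambda_rate + sum_tau2 / 2.0));
          if (lambda2 < 1e-8) lambda2 = 1e-8;
        }
      }
    }
    if ((family == 2 || family == 3) && !pi_fixed) {
      pi = R::rbeta(pi_a + n_in, pi_b + p - n_in);
      if (pi < 1e-8) pi = 1e-8;
      if (pi > 1.0 - 1e-8) pi = 1.0 - 1e-8;
    }

    // residual variance
    if (!ve_fixed) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      if (family == 4 && !vb_fixed) {
        // BL: theta_j ~ N(0, tau2_j var_e) contributes to the var_e conditional
        double st = 0.0;
        for (int j = 0; j < p; ++j) st += theta[j] * theta[j] / tau2[j];
        var_e = rscinv(sse + st, S_e, n + p + df_e);
      } else {
        var_e = rscinv(sse, S_e, n + df_e);
      }
    }

    // store
    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      for (int j = 0; j < p; ++j) {
        out_theta(saved, j) = theta[j];
        delta_mean[j] += delta[j];
        var_j_mean[j] += (family == 1 || family == 2) ? var_j[j]
                         : (family == 4 ? tau2[j] * var_e : var_b);
      }
      out_mu[saved] = mu;
      out_var_e[saved] = var_e;
      out_var_b[saved] = var_b;
      out_pi[saved] = pi;
      out_lambda2[saved] = lambda2;
      ++saved;
    }
  }

  for (int j = 0; j < p; ++j) {
    delta_mean[j] /= n_save;
    var_j_mean[j] /= n_save;
  }

  return List::create(
      _["theta"] = out_theta, _["mu"] = out_mu, _["var_e"] = out_var_e,
      _["var_b"] = out_var_b, _["pi"] = out_pi, _["lambda2"] = out_lambda2,
      _["inclusion_prob"] = delta_mean, _["coef_var_mean"] = var_j_mean,
      _["n_save"] = n_save);
}
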
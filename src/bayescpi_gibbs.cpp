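#include <Rcpp.h>
using namespace Rcpp;

// BayesC(pi) single-site Gibbs sampler.
//
// Model: y_i = mu + sum_j x_ij a_j + e_i, with a_j zero with probability pi
// and N(0, sigma2_a) otherwise; scaled-inverse-chi-square priors on the two
// variances; optional Beta full conditional for pi (uniform prior).
// Residuals are maintained incrementally (e = y - mu - X a), giving O(nM)
// per sweep.  All randomness goes through R's RNG, so set.seed() in R makes
// chains bit-reproducible.
//
// update_order: 0-based SNP order used every sweep when randomize_order is
// false; when true a fresh permutation is drawn each sweep.

// [[Rcpp::export(name = ".bayescpi_gibbs_cpp")]]
List bayescpi_gibbs_cpp(NumericVector y, NumericMatrix X,
                        int n_iter, int burn_in, int thin,
                        double pi_init, bool pi_sampled,
                        double va, double ve, double S2a, double S2e,
                        double sigma2a_init, double sigma2e_init,
                        bool update_sigma2a, bool update_sigma2e,
                        double mu_init, bool sample_mu,
                        bool randomize_order) {
  const int n = y.size();
  const int M = X.ncol();
  if (X.nrow() != n) stop("genotype matrix and phenotype length disagree");
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter");

  std::vector<double> a(M, 0.0), xtx(M);
  for (int j = 0; j < M; ++j) {
    double s = 0.0;
    const double* xj = &X(0, j);
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
  }

  double mu = mu_init;
  double pi = pi_init;
  double sigma2a = sigma2a_init > 0 ? sigma2a_init : 1e-8;
  double sigma2e = sigma2e_init;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  std::vector<int> gamma(M, 0);
  std::vector<int> order(M);
  for (int j = 0; j < M; ++j) order[j] = j;

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  NumericVector effect_sum(M), ppi_sum(M);
  NumericVector mu_chain(n_keep), pi_chain(n_keep),
      s2a_chain(n_keep), s2e_chain(n_keep);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    if (sample_mu) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += e[i] + mu;
      double mu_new = R::rnorm(s / n, std::sqrt(sigma2e / n));
      double d = mu_new - mu;
      for (int i = 0; i < n; ++i) e[i] -= d;
      mu = mu_new;
    }

    if (randomize_order) {
      for (int j = M - 1; j > 0; --j) {
        int k = (int)(unif_rand() * (j + 1));
        std::swap(order[j], order[k]);
      }
    }

    int m_incl = 0;
    double ssq_a = 0.0;
    for (int jj = 0; jj < M; ++jj) {
      const int j = order[jj];
      const double* xj = &X(0, j);
      double rhs = 0.0;
      if (a[j] != 0.0) {
        for (int i = 0; i < n; ++i) { e[i] += xj[i] * a[j]; rhs += xj[i] * e[i]; }
      } else {
        for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
      }
      bool include;
      if (pi >= 1.0 - 1e-12) {
        include = false;
      } else if (pi <= 1e-12) {
        include = true;
      } else {
        // log Bayes factor of inclusion vs exclusion given current residuals
        double t = xtx[j] * sigma2a + sigma2e;
        double log_bf = -0.5 * std::log(t / sigma2e) +
            0.5 * sigma2a * rhs * rhs / (sigma2e * t);
        double log_odds = std::log(1.0 - pi) - std::log(pi) + log_bf;
        double pr = 1.0 / (1.0 + std::exp(-log_odds));
        include = unif_rand() < pr;
      }
      if (include && xtx[j] > 0.0) {
        double lambda = sigma2e / sigma2a;
        double cinv = 1.0 / (xtx[j] + lambda);
        double mean_a = rhs * cinv;
        double sd_a = std::sqrt(sigma2e * cinv);
        a[j] = R::rnorm(mean_a, sd_a);
        for (int i = 0; i < n; ++i) e[i] -= xj[i] * a[j];
        gamma[j] = 1;
        ssq_a += a[j] * a[j];
        ++m_incl;
      } else {
        a[j] = 0.0;
        gamma[j] = 0;
      }
    }

    if (update_sigma2a) {
      double df = va + m_incl;
      sigma2a = (va * S2a + ssq_a) / R::rchisq(df);
      if (!(sigma2a > 1e-12)) sigma2a = 1e-12;
    }
    if (update_sigma2e) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma2e = (ve * S2e + sse) / R::rchisq(ve + n);
      if (!R_finite(sigma2e) || sigma2e <= 0)
        stop("residual variance became non-finite at iteration %d", it + 1);
    }
    if (pi_sampled) {
      pi = R::rbeta((double)(M - m_incl) + 1.0, (double)m_incl + 1.0);
    }

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < M; ++j) {
        effect_sum[j] += a[j];
        ppi_sum[j] += gamma[j];
      }
      mu_chain[kept] = mu;
      pi_chain[kept] = pi;
      s2a_chain[kept] = sigma2a;
      s2e_chain[kept] = sigma2e;
      ++kept;
    }
  }

  NumericVector effect_mean(M), ppi(M);
  for (int j = 0; j < M; ++j) {
    effect_mean[j] = effect_sum[j] / kept;
    ppi[j] = ppi_sum[j] / kept;
  }
  return List::create(_["effect_mean"] = effect_mean,
                      _["ppi"] = ppi,
                      _["mu_chain"] = mu_chain,
                      _["pi_chain"] = pi_chain,
                      _["sigma2_a_chain"] = s2a_chain,
                      _["sigma2_e_chain"] = s2e_chain,
                      _["n_samples"] = kept);
}
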
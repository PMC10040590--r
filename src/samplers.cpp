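#include <Rcpp.h>
using namespace Rcpp;

// All samplers draw through R's RNG so that set.seed() gives bit-identical
// chains. Variance components use the scaled inverse chi-square convention
// sigma2 = (S + SS) / rchisq(df + k), i.e. S is the prior numerator.

static inline double draw_var(double S, double df, double SS, double k) {
  return (S + SS) / R::rchisq(df + k);
}

// Single-environment marker-effect sampler.
// model: 0 = ridge (RR-BLUP), 1 = BayesB, 2 = BayesC.
// W must be centred (and, for ridge, standardized) beforehand; y complete.
// fix_var_a / fix_var_e < 0 mean "sample this variance".
// [[Rcpp::export(name = ".cpp_wgr_marker")]]
List cpp_wgr_marker(NumericVector y, NumericMatrix W, int model,
                    double pi0, double df_a, double S_a,
                    double df_e, double S_e,
                    int n_iter, int burn_in, int thin,
                    double var_a_init, double var_e_init,
                    double fix_var_a, double fix_var_e) {
  const int n = y.size();
  const int m = W.ncol();
  if (W.nrow() != n) stop("nrow(W) must match length(y)");
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in");
  const int n_keep = (n_iter - burn_in) / thin;
  if (n_keep < 1) stop("no posterior draws kept: shorten burn_in or thin");

  std::vector<double> xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    const double *xj = &W(0, j);
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
  }

  double mu = Rcpp::mean(y);
  std::vector<double> alpha(m, 0.0), var_aj(m, var_a_init);
  std::vector<int> incl(m, model == 1 || model == 2 ? 0 : 1);
  double var_a = var_a_init;
  double var_e = var_e_init;
  NumericVector e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  NumericVector alpha_mean(m), pip(m), g_mean(n);
  NumericVector mu_chain(n_keep), var_e_chain(n_keep), var_a_chain(n_keep),
      var_g_chain(n_keep), n_incl_chain(n_keep);
  const double log_prior_odds = std::log(1.0 - pi0) - std::log(pi0);

  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    // intercept (flat prior)
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = mu + ebar + R::norm_rand() * std::sqrt(var_e / n);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    // marker effects, single-site in fixed order
    int n_in = 0;
    for (int j = 0; j < m; ++j) {
      const double *xj = &W(0, j);
      const double a_old = alpha[j];
      double xe = 0.0;
      for (int i = 0; i < n; ++i) xe += xj[i] * e[i];
      const double xr = xe + xtx[j] * a_old;       // x' (residual excluding j)
      const double rhs = xr / var_e;
      double a_new = 0.0;
      if (model == 0) {                             // ridge: always in
        const double C = xtx[j] / var_e + 1.0 / var_a;
        a_new = rhs / C + R::norm_rand() / std::sqrt(C);
        incl[j] = 1;
      } else {
        const double vslab = (model == 1) ? var_aj[j] : var_a;
        const double C = xtx[j] / var_e + 1.0 / vslab;
        const double logR = -0.5 * std::log1p(vslab * xtx[j] / var_e) +
                            0.5 * rhs * rhs / C;
        const double logodds = log_prior_odds + logR;
        const double p_in = 1.0 / (1.0 + std::exp(-logodds));
        if (R::unif_rand() < p_in) {
          a_new = rhs / C + R::norm_rand() / std::sqrt(C);
          incl[j] = 1;
        } else {
          incl[j] = 0;
        }
      }
      if (a_new != a_old) {
        const double d = a_old - a_new;
        for (int i = 0; i < n; ++i) e[i] += xj[i] * d;
        alpha[j] = a_new;
      }
      n_in += incl[j];
      if (model == 1) {                             // per-marker slab variance
        if (incl[j]) var_aj[j] = draw_var(S_a, df_a, alpha[j] * alpha[j], 1.0);
        else var_aj[j] = S_a / R::rchisq(df_a);     // refresh from prior
      }
    }

    if (model == 0) {                               // common ridge variance
      if (fix_var_a >= 0.0) var_a = fix_var_a;
      else {
        double SS = 0.0;
        for (int j = 0; j < m; ++j) SS += alpha[j] * alpha[j];
        var_a = draw_var(S_a, df_a, SS, (double)m);
      }
    } else if (model == 2) {                        // BayesC shared slab
      if (fix_var_a >= 0.0) var_a = fix_var_a;
      else {
        double SS = 0.0; int k = 0;
        for (int j = 0; j < m; ++j) if (incl[j]) { SS += alpha[j] * alpha[j]; ++k; }
        var_a = draw_var(S_a, df_a, SS, (double)k);
      }
    }

    if (fix_var_e >= 0.0) var_e = fix_var_e;
    else {
      double SSE = 0.0;
      for (int i = 0; i < n; ++i) SSE += e[i] * e[i];
      var_e = draw_var(S_e, df_e, SSE, (double)n);
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      double gs = 0.0, gss = 0.0;
      for (int i = 0; i < n; ++i) {
        const double gi = y[i] - mu - e[i];
        g_mean[i] += gi;
        gs += gi; gss += gi * gi;
      }
      const double var_g = (gss - gs * gs / n) / (n - 1.0);
      for (int j = 0; j < m; ++j) { alpha_mean[j] += alpha[j]; pip[j] += incl[j]; }
      mu_chain[kept] = mu;
      var_e_chain[kept] = var_e;
      if (model == 1) {
        double va = 0.0;
        for (int j = 0; j < m; ++j) va += var_aj[j];
        var_a_chain[kept] = va / m;
      } else var_a_chain[kept] = var_a;
      var_g_chain[kept] = var_g;
      n_incl_chain[kept] = n_in;
      ++kept;
    }
  }

  for (int j = 0; j < m; ++j) { alpha_mean[j] /= kept; pip[j] /= kept; }
  for (int i = 0; i < n; ++i) g_mean[i] /= kept;

  return List::create(
      _["alpha"] = alpha_mean, _["pip"] = pip, _["g"] = g_mean,
      _["mu_chain"] = mu_chain, _["var_e_chain"] = var_e_chain,
      _["var_a_chain"] = var_a_chain, _["var_g_chain"] = var_g_chain,
      _["n_incl_chain"] = n_incl_chain, _["n_draws"] = kept);
}

// Marker-by-environment interaction RR-BLUP sampler.
// y is stacked over environments with rows grouped by environment;
// env_off has length L+1 with row offsets (0-based) of each block.
// W holds the per-environment centred/standardized marker rows in the same
// stacked order. Marker effects decompose as alpha0 (shared) + alpha_l.
// fix_var_specific < 0 means "sample the specific variances".
// [[Rcpp::export(name = ".cpp_wgr_mxe")]]
List cpp_wgr_mxe(NumericVector y, IntegerVector env_off, NumericMatrix W,
                 double S_a0, NumericVector S_al, double df_a,
                 NumericVector S_el, double df_e,
                 int n_iter, int burn_in, int thin,
                 double var_a_init, NumericVector var_e_init,
                 double fix_var_specific) {
  const int N = y.size();
  const int m = W.ncol();
  const int L = env_off.size() - 1;
  if (W.nrow() != N) stop("nrow(W) must match length(y)");
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in");
  const int n_keep = (n_iter - burn_in) / thin;
  if (n_keep < 1) stop("no posterior draws kept: shorten burn_in or thin");

  // per-environment x'x for every marker
  std::vector<std::vector<double>> xtx(L, std::vector<double>(m));
  for (int l = 0; l < L; ++l)
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      const double *xj = &W(0, j);
      for (int r = env_off[l]; r < env_off[l + 1]; ++r) s += xj[r] * xj[r];
      xtx[l][j] = s;
    }

  std::vector<double> mu(L), var_e(L), nl(L);
  for (int l = 0; l < L; ++l) {
    double s = 0.0;
    nl[l] = env_off[l + 1] - env_off[l];
    for (int r = env_off[l]; r < env_off[l + 1]; ++r) s += y[r];
    mu[l] = s / nl[l];
    var_e[l] = var_e_init[l];
  }
  std::vector<double> alpha0(m, 0.0);
  std::vector<std::vector<double>> alphal(L, std::vector<double>(m, 0.0));
  double var_a0 = var_a_init;
  std::vector<double> var_al(L, fix_var_specific >= 0.0 ? fix_var_specific
                                                        : var_a_init);
  NumericVector e(N);
  for (int l = 0; l < L; ++l)
    for (int r = env_off[l]; r < env_off[l + 1]; ++r) e[r] = y[r] - mu[l];

  NumericVector alpha0_mean(m), mu_mean(L);
  NumericMatrix alphal_mean(m, L);
  NumericVector var_a0_chain(n_keep);
  NumericMatrix var_al_chain(n_keep, L), var_el_chain(n_keep, L);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // environment intercepts
    for (int l = 0; l < L; ++l) {
      double ebar = 0.0;
      for (int r = env_off[l]; r < env_off[l + 1]; ++r) ebar += e[r];
      ebar /= nl[l];
      const double mu_new = mu[l] + ebar + R::norm_rand() * std::sqrt(var_e[l] / nl[l]);
      const double d = mu_new - mu[l];
      for (int r = env_off[l]; r < env_off[l + 1]; ++r) e[r] -= d;
      mu[l] = mu_new;
    }

    // shared marker effects (precision-weighted across environments)
    for (int j = 0; j < m; ++j) {
      const double *xj = &W(0, j);
      const double a_old = alpha0[j];
      double rhs = 0.0, wsum = 0.0;
      for (int l = 0; l < L; ++l) {
        double xe = 0.0;
        for (int r = env_off[l]; r < env_off[l + 1]; ++r) xe += xj[r] * e[r];
        rhs += xe / var_e[l];
        wsum += xtx[l][j] / var_e[l];
      }
      rhs += a_old * wsum;
      const double C = wsum + 1.0 / var_a0;
      const double a_new = rhs / C + R::norm_rand() / std::sqrt(C);
      const double d = a_old - a_new;
      if (d != 0.0) for (int r = 0; r < N; ++r) e[r] += xj[r] * d;
      alpha0[j] = a_new;
    }

    // environment-specific marker effects
    for (int l = 0; l < L; ++l) {
      for (int j = 0; j < m; ++j) {
        const double *xj = &W(0, j);
        const double a_old = alphal[l][j];
        double xe = 0.0;
        for (int r = env_off[l]; r < env_off[l + 1]; ++r) xe += xj[r] * e[r];
        const double rhs = (xe + xtx[l][j] * a_old) / var_e[l];
        const double C = xtx[l][j] / var_e[l] + 1.0 / var_al[l];
        const double a_new = rhs / C + R::norm_rand() / std::sqrt(C);
        const double d = a_old - a_new;
        if (d != 0.0)
          for (int r = env_off[l]; r < env_off[l + 1]; ++r) e[r] += xj[r] * d;
        alphal[l][j] = a_new;
      }
    }

    // variance components
    {
      double SS = 0.0;
      for (int j = 0; j < m; ++j) SS += alpha0[j] * alpha0[j];
      var_a0 = draw_var(S_a0, df_a, SS, (double)m);
    }
    for (int l = 0; l < L; ++l) {
      if (fix_var_specific >= 0.0) var_al[l] = fix_var_specific;
      else {
        double SS = 0.0;
        for (int j = 0; j < m; ++j) SS += alphal[l][j] * alphal[l][j];
        var_al[l] = draw_var(S_al[l], df_a, SS, (double)m);
      }
      double SSE = 0.0;
      for (int r = env_off[l]; r < env_off[l + 1]; ++r) SSE += e[r] * e[r];
      var_e[l] = draw_var(S_el[l], df_e, SSE, nl[l]);
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < m; ++j) {
        alpha0_mean[j] += alpha0[j];
        for (int l = 0; l < L; ++l) alphal_mean(j, l) += alphal[l][j];
      }
      for (int l = 0; l < L; ++l) {
        mu_mean[l] += mu[l];
        var_al_chain(kept, l) = var_al[l];
        var_el_chain(kept, l) = var_e[l];
      }
      var_a0_chain[kept] = var_a0;
      ++kept;
    }
  }

  for (int j = 0; j < m; ++j) {
    alpha0_mean[j] /= kept;
    for (int l = 0; l < L; ++l) alphal_mean(j, l) /= kept;
  }
  for (int l = 0; l < L; ++l) mu_mean[l] /= kept;

  return List::create(
      _["alpha0"] = alpha0_mean, _["alpha_env"] = alphal_mean,
      _["mu"] = mu_mean, _["var_a0_chain"] = var_a0_chain,
      _["var_al_chain"] = var_al_chain, _["var_el_chain"] = var_el_chain,
      _["n_draws"] = kept);
}
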
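// Adaptive Metropolis-within-Gibbs sampler for the Bayesian Poisson APC
// model. One coordinate at a time gets a Gaussian random-walk proposal whose
// scale adapts toward a 0.44 acceptance rate during burn-in only (frozen
// afterwards, preserving detailed balance); the RW2 precisions get conjugate
// Gamma Gibbs updates. All randomness comes from R's RNG, so runs are
// reproducible from the R-side seed.

#include <Rcpp.h>
using namespace Rcpp;

// log prior contribution of RW2 term t if full-vector position `pos`
// (0-based) takes value `val`: only the affected conditional terms and the
// diffuse baseline on the first two levels are evaluated (constants in tau
// cancel between proposal and current state).
static double rw2_local(const std::vector<double>& x, int n, int pos,
                        double val, double tau, double baseline_sd) {
  double lp = 0.0;
  if (pos < 2) lp += -0.5 * val * val / (baseline_sd * baseline_sd);
  // conditionals with index i (0-based, i >= 2) involve x[i], x[i-1], x[i-2]
  for (int i = pos; i <= pos + 2 && i < n; ++i) {
    if (i < 2) continue;
    double xi = (i == pos) ? val : x[i];
    double xm1 = (i - 1 == pos) ? val : x[i - 1];
    double xm2 = (i - 2 == pos) ? val : x[i - 2];
    double r = xi - 2.0 * xm1 + xm2;
    lp += -0.5 * tau * r * r;
  }
  return lp;
}

// full log prior of beta given current precisions (constants in tau omitted:
// they cancel between proposal and current state at fixed tau)
static double full_log_prior(const std::vector<double>& beta,
                             const std::vector< std::vector<int> >& tmap,
                             const std::vector<double>& tau,
                             const IntegerVector& term_of,
                             const NumericVector& normal_sd,
                             double baseline_sd) {
  double lp = 0.0;
  const int n_par = (int) beta.size();
  for (int j = 0; j < n_par; ++j) {
    if (term_of[j] < 0) {
      double sd = normal_sd[j];
      lp += -0.5 * beta[j] * beta[j] / (sd * sd);
    }
  }
  for (size_t t = 0; t < tmap.size(); ++t) {
    const std::vector<int>& m = tmap[t];
    int n = (int) m.size();
    for (int i = 0; i < n && i < 2; ++i) {
      double xi = m[i] < 0 ? 0.0 : beta[m[i]];
      lp += -0.5 * xi * xi / (baseline_sd * baseline_sd);
    }
    for (int i = 2; i < n; ++i) {
      double xi = m[i] < 0 ? 0.0 : beta[m[i]];
      double xm1 = m[i - 1] < 0 ? 0.0 : beta[m[i - 1]];
      double xm2 = m[i - 2] < 0 ? 0.0 : beta[m[i - 2]];
      double r = xi - 2.0 * xm1 + xm2;
      lp += -0.5 * tau[t] * r * r;
    }
  }
  return lp;
}

// [[Rcpp::export]]
List apc_sampler_cpp(NumericVector y, NumericVector expo, NumericMatrix X,
                     List rw2_terms, IntegerVector term_of,
                     IntegerVector pos_of, NumericVector normal_sd,
                     double baseline_sd, NumericVector init,
                     NumericVector prec_init, NumericVector scale_init,
                     NumericMatrix prop_chol, double global_scale_init,
                     int n_global, int n_burn, int n_keep, int thin,
                     double target_accept, bool adapt) {
  const int n_cells = y.size();
  const int n_par = X.ncol();
  const int n_terms = rw2_terms.size();

  // per-column nonzero structure (X entries are 0/1 indicators)
  std::vector< std::vector<int> > nz(n_par);
  for (int j = 0; j < n_par; ++j)
    for (int i = 0; i < n_cells; ++i)
      if (X(i, j) != 0.0) nz[j].push_back(i);

  // term metadata
  std::vector< std::vector<int> > tmap(n_terms);
  std::vector<double> tshape(n_terms), trate(n_terms);
  std::vector<bool> tfixed(n_terms);
  for (int t = 0; t < n_terms; ++t) {
    List trm = rw2_terms[t];
    IntegerVector m = trm["map"];  // 0-based beta index, -1 = fixed zero
    tmap[t] = std::vector<int>(m.begin(), m.end());
    tshape[t] = as<double>(trm["shape"]);
    trate[t] = as<double>(trm["rate"]);
    tfixed[t] = as<bool>(trm["fixed"]);
  }

  std::vector<double> beta(init.begin(), init.end());
  std::vector<double> tau(prec_init.begin(), prec_init.end());
  std::vector<double> lscale(n_par);
  for (int j = 0; j < n_par; ++j) lscale[j] = std::log(scale_init[j]);

  std::vector<double> eta(n_cells, 0.0);
  for (int j = 0; j < n_par; ++j)
    if (beta[j] != 0.0)
      for (size_t k = 0; k < nz[j].size(); ++k)
        eta[nz[j][k]] += X(nz[j][k], j) * beta[j];
  for (int i = 0; i < n_cells; ++i)
    if (!R_finite(eta[i])) stop("non-finite linear predictor at init");

  // scratch full vector per term (max length)
  size_t maxlen = 1;
  for (int t = 0; t < n_terms; ++t) maxlen = std::max(maxlen, tmap[t].size());
  std::vector<double> xfull(maxlen);

  const int total_iter = n_burn + n_keep * thin;
  NumericMatrix draws(n_keep, n_par);
  NumericMatrix prec_draws(n_keep, n_terms);
  NumericVector loglik(n_keep);
  std::vector<int> acc_batch(n_par, 0), acc_post(n_par, 0);
  int batch_len = 50, batch_count = 0, iter_in_batch = 0, post_iters = 0;
  int stored = 0;
  double lg_global = std::log(global_scale_init);
  std::vector<double> zbuf(n_par), dbuf(n_par), bprop(n_par);
  std::vector<double> etaprop(n_cells);
  int acc_global_batch = 0, acc_global_post = 0;
  int global_tries_batch = 0, global_tries_post = 0;

  for (int iter = 0; iter < total_iter; ++iter) {
    bool burn = iter < n_burn;
    // --- coordinate Metropolis updates ---
    for (int j = 0; j < n_par; ++j) {
      double cur = beta[j];
      double prop = cur + std::exp(lscale[j]) * norm_rand();
      // likelihood delta over the cells this coordinate touches
      double dll = 0.0;
      bool ok = true;
      for (size_t k = 0; k < nz[j].size(); ++k) {
        int i = nz[j][k];
        double d = X(i, j) * (prop - cur);
        double enew = std::exp(eta[i] + d);
        if (!R_finite(enew)) { ok = false; break; }
        dll += y[i] * d - expo[i] * (enew - std::exp(eta[i]));
      }
      if (!ok) continue;  // overflow proposal: reject
      // prior delta
      double dlp;
      int t = term_of[j];
      if (t >= 0) {
        int n = (int) tmap[t].size();
        for (int i2 = 0; i2 < n; ++i2)
          xfull[i2] = tmap[t][i2] < 0 ? 0.0 : beta[tmap[t][i2]];
        int pos = pos_of[j];
        dlp = rw2_local(xfull, n, pos, prop, tau[t], baseline_sd) -
              rw2_local(xfull, n, pos, cur, tau[t], baseline_sd);
      } else {
        double sd = normal_sd[j];
        dlp = -0.5 * (prop * prop - cur * cur) / (sd * sd);
      }
      if (std::log(unif_rand()) < dll + dlp) {
        beta[j] = prop;
        for (size_t k = 0; k < nz[j].size(); ++k)
          eta[nz[j][k]] += X(nz[j][k], j) * (prop - cur);
        acc_batch[j]++;
        if (!burn) acc_post[j]++;
      }
    }
    // --- preconditioned full-vector Gaussian proposals ---
    // direction structure from the (inverse-Hessian-at-mode) Cholesky factor
    // carries the posterior correlations the coordinate sweep cannot follow
    for (int gm = 0; gm < n_global; ++gm) {
      double s = std::exp(lg_global);
      for (int j = 0; j < n_par; ++j) zbuf[j] = norm_rand();
      bool ok = true;
      for (int j = 0; j < n_par; ++j) {
        double dj = 0.0;
        for (int k = 0; k <= j; ++k) dj += prop_chol(j, k) * zbuf[k];
        dbuf[j] = s * dj;
        bprop[j] = beta[j] + dbuf[j];
      }
      double ll_new = 0.0, ll_old = 0.0;
      for (int i = 0; i < n_cells; ++i) {
        double de = 0.0;
        for (int j = 0; j < n_par; ++j)
          if (X(i, j) != 0.0) de += X(i, j) * dbuf[j];
        double en = eta[i] + de;
        double een = std::exp(en);
        if (!R_finite(een)) { ok = false; break; }
        etaprop[i] = en;
        ll_new += y[i] * en - expo[i] * een;
        ll_old += y[i] * eta[i] - expo[i] * std::exp(eta[i]);
      }
      if (ok) {
        double dlp = full_log_prior(bprop, tmap, tau, term_of, normal_sd,
                                    baseline_sd) -
                     full_log_prior(beta, tmap, tau, term_of, normal_sd,
                                    baseline_sd);
        if (std::log(unif_rand()) < (ll_new - ll_old) + dlp) {
          beta = bprop;
          for (int i = 0; i < n_cells; ++i) eta[i] = etaprop[i];
          acc_global_batch++;
          if (!burn) acc_global_post++;
        }
      }
      global_tries_batch++;
      if (!burn) global_tries_post++;
    }
    // --- conjugate Gibbs updates of the RW2 precisions ---
    for (int t = 0; t < n_terms; ++t) {
      if (tfixed[t]) continue;
      int n = (int) tmap[t].size();
      if (n < 3) continue;  // no curvature terms: keep the prior draw fixed
      double ss = 0.0;
      for (int i2 = 2; i2 < n; ++i2) {
        double xi = tmap[t][i2] < 0 ? 0.0 : beta[tmap[t][i2]];
        double xm1 = tmap[t][i2 - 1] < 0 ? 0.0 : beta[tmap[t][i2 - 1]];
        double xm2 = tmap[t][i2 - 2] < 0 ? 0.0 : beta[tmap[t][i2 - 2]];
        double r = xi - 2.0 * xm1 + xm2;
        ss += r * r;
      }
      tau[t] = R::rgamma(tshape[t] + 0.5 * (n - 2), 1.0 / (trate[t] + 0.5 * ss));
    }
    // --- proposal adaptation during burn-in only ---
    if (burn && adapt && ++iter_in_batch == batch_len) {
      batch_count++;
      double step = std::min(0.5, 1.0 / std::sqrt((double) batch_count));
      for (int j = 0; j < n_par; ++j) {
        double rate = (double) acc_batch[j] / batch_len;
        lscale[j] += (rate > target_accept ? step : -step);
        acc_batch[j] = 0;
      }
      if (n_global > 0 && global_tries_batch > 0) {
        double grate = (double) acc_global_batch / global_tries_batch;
        lg_global += (grate > 0.25 ? step : -step);
        acc_global_batch = 0;
        global_tries_batch = 0;
      }
      iter_in_batch = 0;
    }
    if (!burn) {
      post_iters++;
      if ((iter - n_burn + 1) % thin == 0) {
        double ll = 0.0;
        for (int i = 0; i < n_cells; ++i)
          ll += y[i] * eta[i] - expo[i] * std::exp(eta[i]);
        for (int j = 0; j < n_par; ++j) draws(stored, j) = beta[j];
        for (int t = 0; t < n_terms; ++t) prec_draws(stored, t) = tau[t];
        loglik[stored] = ll;
        stored++;
      }
    }
  }

  NumericVector acc_rate(n_par), scales(n_par);
  for (int j = 0; j < n_par; ++j) {
    acc_rate[j] = post_iters > 0 ? (double) acc_post[j] / post_iters : NA_REAL;
    scales[j] = std::exp(lscale[j]);
  }
  double acc_global = global_tries_post > 0 ?
    (double) acc_global_post / global_tries_post : NA_REAL;
  return List::create(_["draws"] = draws, _["prec"] = prec_draws,
                      _["loglik"] = loglik, _["accept_rate"] = acc_rate,
                      _["scales"] = scales,
                      _["accept_rate_global"] = acc_global,
                      _["global_scale"] = std::exp(lg_global));
}
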
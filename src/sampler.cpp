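// Metropolis-within-Gibbs sampler for the many-facet Rasch model.
//
// State is the full parameter set (theta, beta, gamma, d). Category
// parameters are parameterized by their K-2 free components d_2..d_{K-1};
// d_1 = 0 is structural and d_K = -sum(d_2..d_{K-1}), so every draw
// satisfies the identification constraints exactly. Anchored beta/gamma
// entries are held at their fixed values and receive no prior term.
//
// Per-record log-probabilities are cached; each single-parameter update
// touches only the records involving that parameter. Proposal SDs are
// adapted toward a 20-50% acceptance rate during burn-in only.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double record_lp(double eta, int x, const double *D, int K) {
  double s[32];
  double mx = -INFINITY;
  for (int l = 1; l <= K; ++l) {
    s[l] = l * eta - D[l];
    if (s[l] > mx) mx = s[l];
  }
  double sum = 0.0;
  for (int l = 1; l <= K; ++l) sum += std::exp(s[l] - mx);
  return s[x] - mx - std::log(sum);
}

// [[Rcpp::export]]
List mfrm_mwg(IntegerVector ex, IntegerVector task, IntegerVector rater,
              IntegerVector score, int J, int I, int R, int K,
              NumericVector theta0, NumericVector beta0,
              NumericVector gamma0, NumericVector d0,
              LogicalVector beta_fixed, LogicalVector gamma_fixed,
              int iterations, int burn_in, int thin,
              NumericVector prop_sd0) {
  const int n = ex.size();
  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> beta(beta0.begin(), beta0.end());
  std::vector<double> gamma(gamma0.begin(), gamma0.end());
  std::vector<double> d(d0.begin(), d0.end()); // d[0] = d_1 = 0, length K
  const int n_free_d = K > 2 ? K - 2 : 0;

  // cumulative D[k] = sum_{m<=k} d_m, 1-based; D[0] unused
  std::vector<double> D(K + 1, 0.0), Dnew(K + 1, 0.0);
  auto rebuild_D = [&](const std::vector<double> &dd, std::vector<double> &DD) {
    DD[0] = 0.0;
    for (int k = 1; k <= K; ++k) DD[k] = DD[k - 1] + dd[k - 1];
  };
  rebuild_D(d, D);

  // record index lists per entity
  std::vector<std::vector<int>> byJ(J), byI(I), byR(R);
  for (int m = 0; m < n; ++m) {
    byJ[ex[m]].push_back(m);
    byI[task[m]].push_back(m);
    byR[rater[m]].push_back(m);
  }

  std::vector<double> eta(n), lp(n);
  for (int m = 0; m < n; ++m) {
    eta[m] = theta[ex[m]] - beta[task[m]] - gamma[rater[m]];
    lp[m] = record_lp(eta[m], score[m], D.data(), K);
  }

  double sd_th = prop_sd0[0], sd_be = prop_sd0[1], sd_ga = prop_sd0[2],
         sd_d = prop_sd0[3];

  // scratch for proposed per-record lps
  std::vector<double> tmp(n);

  const int n_keep = (iterations > burn_in) ? (iterations - burn_in) / thin : 0;
  NumericMatrix th_draws(n_keep, J), be_draws(n_keep, I), ga_draws(n_keep, R),
      d_draws(n_keep, K);
  int kept = 0;

  // acceptance bookkeeping: [class] totals and adaptation-window counts
  double acc_tot[4] = {0, 0, 0, 0}, att_tot[4] = {0, 0, 0, 0};
  double acc_win[4] = {0, 0, 0, 0}, att_win[4] = {0, 0, 0, 0};

  RNGScope scope;

  auto update_scalar = [&](int cls, double &par, const std::vector<int> &recs,
                           double sgn, double sd_prop, bool with_prior) {
    double delta = norm_rand() * sd_prop;
    double prop = par + delta;
    double dlp = 0.0;
    for (size_t q = 0; q < recs.size(); ++q) {
      int m = recs[q];
      tmp[q] = record_lp(eta[m] + sgn * delta, score[m], D.data(), K);
      dlp += tmp[q] - lp[m];
    }
    if (with_prior) dlp += -0.5 * (prop * prop - par * par);
    att_tot[cls] += 1; att_win[cls] += 1;
    if (std::log(unif_rand()) < dlp) {
      par = prop;
      for (size_t q = 0; q < recs.size(); ++q) {
        int m = recs[q];
        eta[m] += sgn * delta;
        lp[m] = tmp[q];
      }
      acc_tot[cls] += 1; acc_win[cls] += 1;
    }
  };

  for (int it = 1; it <= iterations; ++it) {
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
    for (int j = 0; j < J; ++j)
      update_scalar(0, theta[j], byJ[j], +1.0, sd_th, true);
    for (int i = 0; i < I; ++i)
      if (!beta_fixed[i]) update_scalar(1, beta[i], byI[i], -1.0, sd_be, true);
    for (int r = 0; r < R; ++r)
      if (!gamma_fixed[r]) update_scalar(2, gamma[r], byR[r], -1.0, sd_ga, true);

    if (n_free_d > 0) {
      // joint random-walk proposal on the free components d_2..d_{K-1}
      std::vector<double> dprop(d);
      double prior_diff = 0.0;
      double tail = 0.0;
      for (int k = 1; k <= n_free_d; ++k) { // dprop index k (0-based) = d_{k+1}
        double delta = norm_rand() * sd_d;
        dprop[k] = d[k] + delta;
        prior_diff += -0.5 * (dprop[k] * dprop[k] - d[k] * d[k]);
        tail += dprop[k];
      }
      dprop[K - 1] = -tail;
      rebuild_D(dprop, Dnew);
      double dlp = prior_diff;
      for (int m = 0; m < n; ++m) {
        tmp[m] = record_lp(eta[m], score[m], Dnew.data(), K);
        dlp += tmp[m] - lp[m];
      }
      att_tot[3] += 1; att_win[3] += 1;
      if (std::log(unif_rand()) < dlp) {
        d = dprop;
        D = Dnew;
        for (int m = 0; m < n; ++m) lp[m] = tmp[m];
        acc_tot[3] += 1; acc_win[3] += 1;
      }
    }

    // burn-in adaptation toward 20-50% acceptance
    if (it <= burn_in && it % 50 == 0) {
      double *sds[4] = {&sd_th, &sd_be, &sd_ga, &sd_d};
      for (int c = 0; c < 4; ++c) {
        if (att_win[c] > 0) {
          double rate = acc_win[c] / att_win[c];
          if (rate < 0.20) *sds[c] *= 0.8;
          else if (rate > 0.50) *sds[c] *= 1.25;
          if (*sds[c] < 1e-3) *sds[c] = 1e-3;
          if (*sds[c] > 5.0) *sds[c] = 5.0;
        }
        acc_win[c] = att_win[c] = 0;
      }
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < J; ++j) th_draws(kept, j) = theta[j];
      for (int i = 0; i < I; ++i) be_draws(kept, i) = beta[i];
      for (int r = 0; r < R; ++r) ga_draws(kept, r) = gamma[r];
      for (int k = 0; k < K; ++k) d_draws(kept, k) = d[k];
      ++kept;
    }
  }

  NumericVector acc(4);
  for (int c = 0; c < 4; ++c)
    acc[c] = att_tot[c] > 0 ? acc_tot[c] / att_tot[c] : NA_REAL;
  acc.names() = CharacterVector::create("theta", "beta", "gamma", "d");

  return List::create(
      _["theta"] = th_draws, _["beta"] = be_draws, _["gamma"] = ga_draws,
      _["d"] = d_draws, _["acceptance"] = acc,
      _["prop_sd"] = NumericVector::create(sd_th, sd_be, sd_ga, sd_d),
      _["n_kept"] = kept);
}
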
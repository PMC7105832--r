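// Metropolis-within-Gibbs samplers for diagnostic classification models with
// rater effects.
//
// facets_mwg: standard LCDM/DINA (eta fixed at zero) and the facets model
//   (additive rater severity inside the logit). Latent class membership is a
//   Gibbs draw from its categorical full conditional; item coefficients and
//   severities are random-walk Metropolis steps with burn-in-only step-size
//   adaptation; class weights are a conjugate Dirichlet draw.
//
// hrm_mwg: hierarchical rater model with the latent ideal category
//   marginalized analytically out of every full conditional (two-term sum
//   per ratee-item response), so the chain state is (class memberships,
//   item coefficients, rater severities/variabilities, class weights).
//
// All randomness comes from R's RNG, so set.seed() on the R side makes runs
// reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}
static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Latent-class weight update. Modes: 0 = fixed uniform (independent
// Bernoulli(0.5) attributes), 1 = saturated categorical with Dirichlet(1)
// prior, 2 = independent attribute rates with Beta(1, 1) priors.
static void update_class_weights(int weight_mode, int N, int C,
                                 const std::vector<int>& z,
                                 const IntegerMatrix& pat,
                                 std::vector<double>& w,
                                 std::vector<double>& logw) {
  if (weight_mode == 0) return;
  if (weight_mode == 1) {
    std::vector<double> cnt(C, 0.0);
    for (int i = 0; i < N; ++i) cnt[z[i]] += 1.0;
    double tot = 0.0;
    for (int c = 0; c < C; ++c) { w[c] = R::rgamma(1.0 + cnt[c], 1.0); tot += w[c]; }
    for (int c = 0; c < C; ++c) { w[c] /= tot; logw[c] = std::log(w[c]); }
  } else {
    const int K = pat.ncol();
    std::vector<double> pk(K);
    for (int k = 0; k < K; ++k) {
      double m = 0.0;
      for (int i = 0; i < N; ++i) m += pat(z[i], k);
      pk[k] = R::rbeta(1.0 + m, 1.0 + N - m);
    }
    for (int c = 0; c < C; ++c) {
      double lw = 0.0;
      for (int k = 0; k < K; ++k)
        lw += pat(c, k) == 1 ? std::log(pk[k]) : std::log1p(-pk[k]);
      logw[c] = lw; w[c] = std::exp(lw);
    }
  }
}

// kernel monotonicity over the class lattice: for every class pair that
// differs by mastering one extra attribute, the kernel must not decrease.
// pairs is 2 x npairs (0-based lower/upper class indices).
static inline bool kernel_monotone(const std::vector<double>& kcol,
                                   const IntegerMatrix& pairs) {
  for (int s = 0; s < pairs.ncol(); ++s)
    if (kcol[pairs(1, s)] < kcol[pairs(0, s)] - 1e-12) return false;
  return true;
}

// sample from unnormalized log weights; fills probs with the normalized
// conditional (used for Rao-Blackwellized mastery probabilities)
static inline int sample_class(const std::vector<double>& ll, int C,
                               std::vector<double>& probs) {
  double mx = ll[0];
  for (int c = 1; c < C; ++c) if (ll[c] > mx) mx = ll[c];
  double tot = 0.0;
  for (int c = 0; c < C; ++c) { probs[c] = std::exp(ll[c] - mx); tot += probs[c]; }
  double u = unif_rand() * tot, acc = 0.0;
  int pick = C - 1;
  for (int c = 0; c < C; ++c) {
    acc += probs[c];
    if (u <= acc) { pick = c; break; }
  }
  for (int c = 0; c < C; ++c) probs[c] /= tot;
  return pick;
}

struct StepAdapter {
  std::vector<double> lstep;
  std::vector<int> acc_b, try_b;    // within current adaptation batch
  std::vector<long> acc_p, try_p;   // post-burn-in (reported)
  StepAdapter(int n, double init) :
    lstep(n, std::log(init)), acc_b(n, 0), try_b(n, 0), acc_p(n, 0), try_p(n, 0) {}
  void record(int p, bool accepted, bool adapting) {
    if (adapting) { try_b[p]++; if (accepted) acc_b[p]++; }
    else          { try_p[p]++; if (accepted) acc_p[p]++; }
  }
  void adapt_batch() {
    for (size_t p = 0; p < lstep.size(); ++p) {
      if (try_b[p] == 0) continue;
      double rate = (double)acc_b[p] / try_b[p];
      double d = rate - 0.4;
      if (d > 0.25) d = 0.25; else if (d < -0.25) d = -0.25;
      lstep[p] += d;
      acc_b[p] = 0; try_b[p] = 0;
    }
  }
};

// [[Rcpp::export]]
List facets_mwg(IntegerMatrix X,          // N x (J*R); -1 = not rated
                NumericMatrix Z,          // C x P class design (item blocks)
                IntegerVector offsets,    // length J+1, 0-based block bounds
                IntegerVector ptype,      // 0 intercept, 1 positive, 2 free
                int R,
                NumericVector prior_sd,   // per coefficient
                double eta_sd,
                bool update_coef, bool update_eta, int weight_mode,
                bool prior_only, int n_sub,
                int n_iter, int burnin, int thin,
                NumericVector coef0, NumericVector eta0, IntegerVector z0,
                IntegerMatrix pat, IntegerMatrix mono_pairs) {
  const int N = X.nrow(), JR = X.ncol(), C = Z.nrow(), P = Z.ncol();
  const int J = offsets.size() - 1;
  if (JR != J * R) stop("X columns must equal J * R");
  if (burnin >= n_iter) stop("burn-in must be shorter than the chain");

  std::vector<double> coef(coef0.begin(), coef0.end());
  std::vector<double> eta(eta0.begin(), eta0.end());
  std::vector<int> z(N);
  for (int i = 0; i < N; ++i) z[i] = z0[i] - 1;
  std::vector<double> w(C, 1.0 / C), logw(C, -std::log((double)C));

  // kernel[j*C + c]
  std::vector<double> kernel(J * C, 0.0);
  auto item_kernel = [&](int j) {
    for (int c = 0; c < C; ++c) {
      double v = 0.0;
      for (int p = offsets[j]; p < offsets[j + 1]; ++p) v += Z(c, p) * coef[p];
      kernel[j * C + c] = v;
    }
  };
  for (int j = 0; j < J; ++j) item_kernel(j);

  // flattened observations grouped by ratee
  std::vector<int> row_ptr(N + 1, 0), obs_jr, obs_x;
  {
    std::vector<int> cnt(N, 0);
    for (int i = 0; i < N; ++i)
      for (int jr = 0; jr < JR; ++jr) if (X(i, jr) >= 0) cnt[i]++;
    for (int i = 0; i < N; ++i) row_ptr[i + 1] = row_ptr[i] + cnt[i];
    obs_jr.resize(row_ptr[N]); obs_x.resize(row_ptr[N]);
    std::vector<int> pos(row_ptr.begin(), row_ptr.end() - 1);
    for (int i = 0; i < N; ++i)
      for (int jr = 0; jr < JR; ++jr)
        if (X(i, jr) >= 0) { obs_jr[pos[i]] = jr; obs_x[pos[i]] = X(i, jr); pos[i]++; }
  }

  std::vector<double> lp1(JR * C), lp0(JR * C);
  std::vector<double> scnt(J * C * R), ncnt(J * C * R);
  auto cell = [&](int j, int c, int r) { return (j * C + c) * R + r; };

  // log-likelihood of item j's grouped data for a candidate kernel column
  auto item_loglik = [&](int j, const std::vector<double>& kcol) {
    double ll = 0.0;
    for (int c = 0; c < C; ++c) {
      for (int r = 0; r < R; ++r) {
        double n = ncnt[cell(j, c, r)];
        if (n == 0.0) continue;
        double s = scnt[cell(j, c, r)];
        double l = kcol[c] - eta[r];
        ll += -s * softplus(-l) - (n - s) * softplus(l);
      }
    }
    return ll;
  };
  auto rater_loglik = [&](int r, double e) {
    double ll = 0.0;
    for (int j = 0; j < J; ++j)
      for (int c = 0; c < C; ++c) {
        double n = ncnt[cell(j, c, r)];
        if (n == 0.0) continue;
        double s = scnt[cell(j, c, r)];
        double l = kernel[j * C + c] - e;
        ll += -s * softplus(-l) - (n - s) * softplus(l);
      }
    return ll;
  };

  StepAdapter ad_coef(P, 0.5), ad_eta(R, 0.3);
  const int n_kept = (n_iter - burnin + thin - 1) / thin;
  NumericMatrix draws(n_kept, P + R + C);
  IntegerMatrix z_draws(n_kept, N);
  NumericMatrix cls_sum(N, C);
  std::vector<double> ll_i(C), probs(C), kcand(C);
  int kept = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    bool adapting = iter < burnin;
    bool record = !adapting && ((iter - burnin) % thin == 0);

    // --- latent class Gibbs draw + sufficient statistics
    std::fill(scnt.begin(), scnt.end(), 0.0);
    std::fill(ncnt.begin(), ncnt.end(), 0.0);
    if (!prior_only) {
      for (int jr = 0; jr < JR; ++jr) {
        int j = jr / R, r = jr % R;
        for (int c = 0; c < C; ++c) {
          double l = kernel[j * C + c] - eta[r];
          lp1[jr * C + c] = -softplus(-l);
          lp0[jr * C + c] = -softplus(l);
        }
      }
      for (int i = 0; i < N; ++i) {
        for (int c = 0; c < C; ++c) ll_i[c] = logw[c];
        for (int t = row_ptr[i]; t < row_ptr[i + 1]; ++t) {
          const double* tab = (obs_x[t] == 1 ? &lp1[obs_jr[t] * C]
                                             : &lp0[obs_jr[t] * C]);
          for (int c = 0; c < C; ++c) ll_i[c] += tab[c];
        }
        z[i] = sample_class(ll_i, C, probs);
        if (record) for (int c = 0; c < C; ++c) cls_sum(i, c) += probs[c];
        for (int t = row_ptr[i]; t < row_ptr[i + 1]; ++t) {
          int jr = obs_jr[t], j = jr / R, r = jr % R;
          ncnt[cell(j, z[i], r)] += 1.0;
          scnt[cell(j, z[i], r)] += obs_x[t];
        }
      }
    }

    // --- item coefficients and severities; several cheap Metropolis
    // sub-cycles per (expensive) class-membership draw improve mixing along
    // flat ridges of the item-parameter posterior
    for (int sub = 0; sub < n_sub; ++sub) {
    if (update_coef) {
      for (int j = 0; j < J; ++j) {
        double lcur = prior_only ? 0.0 : item_loglik(j, std::vector<double>(
            kernel.begin() + j * C, kernel.begin() + (j + 1) * C));
        for (int p = offsets[j]; p < offsets[j + 1]; ++p) {
          double step = std::exp(ad_coef.lstep[p]);
          double prop = coef[p] + step * norm_rand();
          if (ptype[p] == 1 && prop <= 0.0) {   // truncated prior: reject
            ad_coef.record(p, false, adapting);
            continue;
          }
          double lnew = 0.0;
          {
            double dv = prop - coef[p];
            for (int c = 0; c < C; ++c)
              kcand[c] = kernel[j * C + c] + Z(c, p) * dv;
          }
          if (ptype[p] != 0 && !kernel_monotone(kcand, mono_pairs)) {
            ad_coef.record(p, false, adapting);   // outside the monotone prior
            continue;
          }
          if (!prior_only) lnew = item_loglik(j, kcand);
          double lpr = -0.5 * (prop * prop - coef[p] * coef[p]) /
                       (prior_sd[p] * prior_sd[p]);
          bool ok = std::log(unif_rand()) < (lnew - lcur + lpr);
          if (ok) {
            coef[p] = prop;
            if (!prior_only) {
              for (int c = 0; c < C; ++c) kernel[j * C + c] = kcand[c];
              lcur = lnew;
            }
          }
          ad_coef.record(p, ok, adapting);
        }
      }
    }

    // --- rater severities
    if (update_eta) {
      for (int r = 0; r < R; ++r) {
        double step = std::exp(ad_eta.lstep[r]);
        double prop = eta[r] + step * norm_rand();
        double lcur = prior_only ? 0.0 : rater_loglik(r, eta[r]);
        double lnew = prior_only ? 0.0 : rater_loglik(r, prop);
        double lpr = -0.5 * (prop * prop - eta[r] * eta[r]) / (eta_sd * eta_sd);
        bool ok = std::log(unif_rand()) < (lnew - lcur + lpr);
        if (ok) eta[r] = prop;
        ad_eta.record(r, ok, adapting);
      }
      // zero-mean identification: recenter severities and shift intercepts
      // by the same amount -- an exact reparameterization (likelihood
      // invariant), so kernels shift wholesale
      double m = 0.0;
      for (int r = 0; r < R; ++r) m += eta[r];
      m /= R;
      if (m != 0.0) {
        for (int r = 0; r < R; ++r) eta[r] -= m;
        for (int p = 0; p < P; ++p) if (ptype[p] == 0) coef[p] -= m;
        for (size_t t = 0; t < kernel.size(); ++t) kernel[t] -= m;
      }
    }
    }  // sub-cycles

    // --- class weights (conjugate Dirichlet under the uniform prior)
    if (!prior_only) {
      update_class_weights(weight_mode, N, C, z, pat, w, logw);
    }

    if (adapting && (iter + 1) % 50 == 0) {
      ad_coef.adapt_batch();
      ad_eta.adapt_batch();
    }
    if (record) {
      for (int p = 0; p < P; ++p) draws(kept, p) = coef[p];
      for (int r = 0; r < R; ++r) draws(kept, P + r) = eta[r];
      for (int c = 0; c < C; ++c) draws(kept, P + R + c) = w[c];
      for (int i = 0; i < N; ++i) z_draws(kept, i) = z[i] + 1;
      kept++;
    }
  }

  NumericVector acc(P + R);
  for (int p = 0; p < P; ++p)
    acc[p] = ad_coef.try_p[p] ? (double)ad_coef.acc_p[p] / ad_coef.try_p[p]
                              : NA_REAL;
  for (int r = 0; r < R; ++r)
    acc[P + r] = ad_eta.try_p[r] ? (double)ad_eta.acc_p[r] / ad_eta.try_p[r]
                                 : NA_REAL;
  if (kept > 0) for (int i = 0; i < N; ++i)
    for (int c = 0; c < C; ++c) cls_sum(i, c) /= kept;
  return List::create(_["draws"] = draws, _["z_draws"] = z_draws,
                      _["cls_probs"] = cls_sum, _["accept"] = acc);
}

// rating-stage probability P(k = 1 | xi) in closed form
static inline double rate_p1(int xi, double phi, double psi) {
  return inv_logit((2.0 * (xi - phi) - 1.0) / (2.0 * psi * psi));
}

// [[Rcpp::export]]
List hrm_mwg(IntegerVector oi, IntegerVector oj, IntegerVector orr,
             IntegerVector ok,               // 0-based indices; scores 0/1
             int N, int J, int R,
             NumericMatrix Z, IntegerVector offsets, IntegerVector ptype,
             NumericVector prior_sd, double phi_sd, double logpsi_sd,
             bool update_coef, bool update_rater, int weight_mode,
             bool prior_only, int n_sub,
             int n_iter, int burnin, int thin,
             NumericVector coef0, NumericVector phi0, NumericVector psi0,
             IntegerVector z0, IntegerMatrix pat, IntegerMatrix mono_pairs) {
  const int C = Z.nrow(), P = Z.ncol(), M = oi.size();
  if (burnin >= n_iter) stop("burn-in must be shorter than the chain");

  std::vector<double> coef(coef0.begin(), coef0.end());
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> psi(psi0.begin(), psi0.end());
  std::vector<int> z(N);
  for (int i = 0; i < N; ++i) z[i] = z0[i] - 1;
  std::vector<double> w(C, 1.0 / C), logw(C, -std::log((double)C));

  std::vector<double> kernel(J * C, 0.0), pi(J * C, 0.5);
  auto refresh_item = [&](int j) {
    for (int c = 0; c < C; ++c) {
      double v = 0.0;
      for (int p = offsets[j]; p < offsets[j + 1]; ++p) v += Z(c, p) * coef[p];
      kernel[j * C + c] = v;
      pi[j * C + c] = inv_logit(v);
    }
  };
  for (int j = 0; j < J; ++j) refresh_item(j);

  // rating-stage tables and per-cell factor products A1/A0 (natural scale;
  // at most a handful of raters per response, so no underflow risk)
  std::vector<double> f1(R), f0(R);   // P(k=1 | xi=1), P(k=1 | xi=0)
  for (int r = 0; r < R; ++r) { f1[r] = rate_p1(1, phi[r], psi[r]);
                                f0[r] = rate_p1(0, phi[r], psi[r]); }
  std::vector<double> A1(N * J, 1.0), A0(N * J, 1.0), curlog(N * J, 0.0);
  auto cidx = [&](int i, int j) { return j * N + i; };
  for (int t = 0; t < M; ++t) {
    int id = cidx(oi[t], oj[t]);
    A1[id] *= (ok[t] == 1 ? f1[orr[t]] : 1.0 - f1[orr[t]]);
    A0[id] *= (ok[t] == 1 ? f0[orr[t]] : 1.0 - f0[orr[t]]);
  }
  std::vector<std::vector<int> > robs(R);
  for (int t = 0; t < M; ++t) robs[orr[t]].push_back(t);

  auto mixlog = [&](int j, int c, int id) {
    double p = pi[j * C + c];
    return std::log(p * A1[id] + (1.0 - p) * A0[id]);
  };
  auto refresh_curlog = [&]() {
    for (int j = 0; j < J; ++j)
      for (int i = 0; i < N; ++i)
        curlog[cidx(i, j)] = mixlog(j, z[i], cidx(i, j));
  };
  refresh_curlog();

  StepAdapter ad_coef(P, 0.5), ad_phi(R, 0.3), ad_psi(R, 0.3);
  const int n_kept = (n_iter - burnin + thin - 1) / thin;
  NumericMatrix draws(n_kept, P + 2 * R + C);
  IntegerMatrix z_draws(n_kept, N);
  NumericMatrix cls_sum(N, C);
  std::vector<double> ll_i(C), probs(C), pin(C), scratch_log(N);
  int kept = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    bool adapting = iter < burnin;
    bool record = !adapting && ((iter - burnin) % thin == 0);

    // --- latent class Gibbs draw (latent category marginalized per item)
    if (!prior_only) {
      for (int i = 0; i < N; ++i) {
        for (int c = 0; c < C; ++c) ll_i[c] = logw[c];
        for (int j = 0; j < J; ++j) {
          double a1 = A1[cidx(i, j)], a0 = A0[cidx(i, j)];
          const double* pj = &pi[j * C];
          for (int c = 0; c < C; ++c)
            ll_i[c] += std::log(pj[c] * a1 + (1.0 - pj[c]) * a0);
        }
        z[i] = sample_class(ll_i, C, probs);
        if (record) for (int c = 0; c < C; ++c) cls_sum(i, c) += probs[c];
        for (int j = 0; j < J; ++j)
          curlog[cidx(i, j)] = mixlog(j, z[i], cidx(i, j));
      }
    }

    for (int sub = 0; sub < n_sub; ++sub) {
    // --- item coefficients
    if (update_coef) {
      for (int j = 0; j < J; ++j) {
        for (int p = offsets[j]; p < offsets[j + 1]; ++p) {
          double step = std::exp(ad_coef.lstep[p]);
          double prop = coef[p] + step * norm_rand();
          if (ptype[p] == 1 && prop <= 0.0) {
            ad_coef.record(p, false, adapting);
            continue;
          }
          double dlik = 0.0;
          {
            double dv = prop - coef[p];
            for (int c = 0; c < C; ++c)
              pin[c] = kernel[j * C + c] + Z(c, p) * dv;   // kernel scale
          }
          if (ptype[p] != 0 && !kernel_monotone(pin, mono_pairs)) {
            ad_coef.record(p, false, adapting);
            continue;
          }
          if (!prior_only) {
            for (int c = 0; c < C; ++c) pin[c] = inv_logit(pin[c]);
            for (int i = 0; i < N; ++i) {
              int id = cidx(i, j);
              double pc = pin[z[i]];
              scratch_log[i] = std::log(pc * A1[id] + (1.0 - pc) * A0[id]);
              dlik += scratch_log[i] - curlog[id];
            }
          }
          double lpr = -0.5 * (prop * prop - coef[p] * coef[p]) /
                       (prior_sd[p] * prior_sd[p]);
          bool okacc = std::log(unif_rand()) < (dlik + lpr);
          if (okacc) {
            coef[p] = prop;
            if (!prior_only) {
              refresh_item(j);
              for (int i = 0; i < N; ++i) curlog[cidx(i, j)] = scratch_log[i];
            }
          }
          ad_coef.record(p, okacc, adapting);
        }
      }
    }

    // --- rater severity and (log) variability
    if (update_rater) {
      for (int r = 0; r < R; ++r) {
        for (int which = 0; which < 2; ++which) {
          StepAdapter& ad = (which == 0 ? ad_phi : ad_psi);
          double step = std::exp(ad.lstep[r]);
          double phip = phi[r], psip = psi[r], lpr;
          if (which == 0) {
            phip = phi[r] + step * norm_rand();
            lpr = -0.5 * (phip * phip - phi[r] * phi[r]) / (phi_sd * phi_sd);
          } else {
            double lp_cur = std::log(psi[r]);
            double lp_new = lp_cur + step * norm_rand();
            psip = std::exp(lp_new);
            lpr = -0.5 * (lp_new * lp_new - lp_cur * lp_cur) /
                  (logpsi_sd * logpsi_sd);
          }
          double g1 = rate_p1(1, phip, psip), g0 = rate_p1(0, phip, psip);
          double dlik = 0.0;
          std::vector<double> na1(robs[r].size()), na0(robs[r].size()),
              nlg(robs[r].size());
          if (!prior_only) {
            for (size_t u = 0; u < robs[r].size(); ++u) {
              int t = robs[r][u];
              int id = cidx(oi[t], oj[t]);
              double old1 = (ok[t] == 1 ? f1[r] : 1.0 - f1[r]);
              double old0 = (ok[t] == 1 ? f0[r] : 1.0 - f0[r]);
              double new1 = (ok[t] == 1 ? g1 : 1.0 - g1);
              double new0 = (ok[t] == 1 ? g0 : 1.0 - g0);
              na1[u] = A1[id] / old1 * new1;
              na0[u] = A0[id] / old0 * new0;
              double p = pi[oj[t] * C + z[oi[t]]];
              nlg[u] = std::log(p * na1[u] + (1.0 - p) * na0[u]);
              dlik += nlg[u] - curlog[id];
            }
          }
          bool okacc = std::log(unif_rand()) < (dlik + lpr);
          if (okacc) {
            phi[r] = phip; psi[r] = psip; f1[r] = g1; f0[r] = g0;
            if (!prior_only) {
              for (size_t u = 0; u < robs[r].size(); ++u) {
                int t = robs[r][u];
                int id = cidx(oi[t], oj[t]);
                A1[id] = na1[u]; A0[id] = na0[u]; curlog[id] = nlg[u];
              }
            }
          }
          ad.record(r, okacc, adapting);
        }
      }
    }
    }  // sub-cycles

    // --- class weights
    if (!prior_only) {
      update_class_weights(weight_mode, N, C, z, pat, w, logw);
    }

    if (adapting && (iter + 1) % 50 == 0) {
      ad_coef.adapt_batch(); ad_phi.adapt_batch(); ad_psi.adapt_batch();
    }
    if (record) {
      for (int p = 0; p < P; ++p) draws(kept, p) = coef[p];
      for (int r = 0; r < R; ++r) draws(kept, P + r) = phi[r];
      for (int r = 0; r < R; ++r) draws(kept, P + R + r) = psi[r];
      for (int c = 0; c < C; ++c) draws(kept, P + 2 * R + c) = w[c];
      for (int i = 0; i < N; ++i) z_draws(kept, i) = z[i] + 1;
      kept++;
    }
  }

  NumericVector acc(P + 2 * R);
  for (int p = 0; p < P; ++p)
    acc[p] = ad_coef.try_p[p] ? (double)ad_coef.acc_p[p] / ad_coef.try_p[p]
                              : NA_REAL;
  for (int r = 0; r < R; ++r) {
    acc[P + r] = ad_phi.try_p[r] ? (double)ad_phi.acc_p[r] / ad_phi.try_p[r]
                                 : NA_REAL;
    acc[P + R + r] = ad_psi.try_p[r] ? (double)ad_psi.acc_p[r] / ad_psi.try_p[r]
                                     : NA_REAL;
  }
  if (kept > 0) for (int i = 0; i < N; ++i)
    for (int c = 0; c < C; ++c) cls_sum(i, c) /= kept;
  return List::create(_["draws"] = draws, _["z_draws"] = z_draws,
                      _["cls_probs"] = cls_sum, _["accept"] = acc);
}
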
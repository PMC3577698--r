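// Adaptive Metropolis-within-Gibbs sampler for the hierarchical matched
// case-control models.  Location parameters move by random-walk Metropolis
// with per-component step scales adapted toward a target acceptance rate
// during burn-in and frozen afterwards; the SNP-effect means, the
// heterogeneity variances and the area/pair variances use their conjugate
// normal-normal and gamma-precision full conditionals.
//
// Uses R's RNG throughout, so set.seed() on the R side fixes the chain.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// y*eta - log(1 + exp(eta)), overflow-safe
static inline double ll_term(int y, double eta) {
  double m = eta > 0.0 ? eta : 0.0;
  return y * eta - (m + std::log1p(std::exp(-std::fabs(eta))));
}

struct CondLik {
  // per-set log-sum-exp bookkeeping for the conditional likelihood
  const std::vector<std::vector<int> >& set_members;
  const std::vector<int>& case_of_set;
  std::vector<double> setll;

  CondLik(const std::vector<std::vector<int> >& sm, const std::vector<int>& cs)
    : set_members(sm), case_of_set(cs), setll(sm.size(), 0.0) {}

  double set_value(const std::vector<double>& psi, int p) const {
    const std::vector<int>& mem = set_members[p];
    double m = psi[mem[0]];
    for (size_t j = 1; j < mem.size(); ++j)
      if (psi[mem[j]] > m) m = psi[mem[j]];
    double s = 0.0;
    for (size_t j = 0; j < mem.size(); ++j)
      s += std::exp(psi[mem[j]] - m);
    return psi[case_of_set[p]] - (m + std::log(s));
  }

  void refresh(const std::vector<double>& psi) {
    for (size_t p = 0; p < set_members.size(); ++p)
      setll[p] = set_value(psi, p);
  }

  double total() const {
    double s = 0.0;
    for (size_t p = 0; p < setll.size(); ++p) s += setll[p];
    return s;
  }
};

// one adaptive random-walk scale + acceptance bookkeeping per component
struct Adapt {
  std::vector<double> scale;
  std::vector<int> win_acc, win_n, tot_acc, tot_n;
  int window;
  double target;
  bool frozen;
  Adapt(int k, int window_, double target_)
    : scale(k, 0.5), win_acc(k, 0), win_n(k, 0), tot_acc(k, 0), tot_n(k, 0),
      window(window_), target(target_), frozen(false) {}
  void record(int j, bool acc) {
    if (frozen) { tot_n[j]++; if (acc) tot_acc[j]++; return; }
    win_n[j]++; if (acc) win_acc[j]++;
    if (win_n[j] >= window) {
      double rate = (double)win_acc[j] / win_n[j];
      double step = rate - target;
      if (step > 0.5) step = 0.5;
      if (step < -0.5) step = -0.5;
      scale[j] *= std::exp(step);
      if (scale[j] < 1e-4) scale[j] = 1e-4;
      if (scale[j] > 50.0) scale[j] = 50.0;
      win_n[j] = 0; win_acc[j] = 0;
    }
  }
};

// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(IntegerMatrix S, NumericMatrix X, NumericMatrix Inter,
                   IntegerVector y, IntegerVector cat0, IntegerVector set0,
                   IntegerVector set_cat0, bool conditional, bool ge,
                   double v0, NumericVector prior_tau, NumericVector prior_area,
                   NumericVector prior_pair, int n_iter, int burn_in, int thin,
                   int adapt_window, double target_acc) {
  const int n = S.nrow(), G = S.ncol(), K = Inter.ncol(), Q = X.ncol();
  int C = 0, P = 0;
  for (int i = 0; i < n; ++i) {
    if (cat0[i] + 1 > C) C = cat0[i] + 1;
    if (set0[i] + 1 > P) P = set0[i] + 1;
  }

  // membership indices
  std::vector<std::vector<int> > cat_members(C), set_members(P), cat_sets(C);
  std::vector<int> case_of_set(P, -1);
  for (int i = 0; i < n; ++i) {
    cat_members[cat0[i]].push_back(i);
    set_members[set0[i]].push_back(i);
    if (y[i] == 1) case_of_set[set0[i]] = i;
  }
  for (int p = 0; p < P; ++p) cat_sets[set_cat0[p]].push_back(p);
  // subjects with nonzero design value, per SNP x category and per SNP
  std::vector<std::vector<std::vector<int> > > gc_members(
      G, std::vector<std::vector<int> >(C));
  std::vector<std::vector<int> > g_members(G);
  for (int i = 0; i < n; ++i)
    for (int g = 0; g < G; ++g)
      if (S(i, g) != 0) {
        gc_members[g][cat0[i]].push_back(i);
        g_members[g].push_back(i);
      }
  std::vector<std::vector<int> > k_members(K);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < n; ++i)
      if (Inter(i, k) != 0.0) k_members[k].push_back(i);
  // scratch flags for de-duplicating affected sets (conditional model)
  std::vector<int> setflag(P, -1);
  int flagtick = 0;

  // parameter state
  double alpha = 0.0, var_area = 1.0, var_pair = 1.0;
  std::vector<std::vector<double> > beta(G, std::vector<double>(C, 0.0));
  std::vector<double> mu(G, 0.0), tau2(G, 1.0), gam(K, 0.0), del(Q, 0.0);
  std::vector<double> a(C, 0.0), b(P, 0.0);

  // linear predictor (eta unconditional / psi conditional)
  std::vector<double> eta(n, 0.0);
  CondLik cl(set_members, case_of_set);

  // rebuild eta from the current state
  // (also used periodically to wash out additive-update rounding drift)
  struct {
    void operator()(std::vector<double>& eta, const IntegerMatrix& S,
                    const NumericMatrix& X, const NumericMatrix& Inter,
                    const IntegerVector& cat0, const IntegerVector& set0,
                    bool conditional, bool ge, double alpha,
                    const std::vector<std::vector<double> >& beta,
                    const std::vector<double>& mu, const std::vector<double>& gam,
                    const std::vector<double>& del, const std::vector<double>& a,
                    const std::vector<double>& b) const {
      const int n = S.nrow(), G = S.ncol(), K = Inter.ncol(), Q = X.ncol();
      for (int i = 0; i < n; ++i) {
        double e = 0.0;
        for (int g = 0; g < G; ++g)
          if (S(i, g) != 0)
            e += (ge ? beta[g][cat0[i]] : mu[g]) * S(i, g);
        for (int k = 0; k < K; ++k) e += gam[k] * Inter(i, k);
        for (int q = 0; q < Q; ++q) e += del[q] * X(i, q);
        if (!conditional) e += alpha + a[cat0[i]] + b[set0[i]];
        eta[i] = e;
      }
    }
  } rebuild;
  rebuild(eta, S, X, Inter, cat0, set0, conditional, ge, alpha, beta, mu,
          gam, del, a, b);
  if (conditional) cl.refresh(eta);

  // Metropolis component index map
  // [alpha] [beta GxC or mu G] [gamma K] [delta Q] [a C] [b P]
  int n_beta = ge ? G * C : G;
  int off_beta = conditional ? 0 : 1;
  int off_gam = off_beta + n_beta;
  int off_del = off_gam + K;
  int off_a = off_del + Q;
  int off_b = off_a + C;
  int n_comp = conditional ? off_del + Q : off_b + P;
  Adapt ad(n_comp, adapt_window, target_acc);

  const double tau_sh = prior_tau[0], tau_rt = prior_tau[1];
  const double area_sh = prior_area[0], area_rt = prior_area[1];
  const double pair_sh = prior_pair[0], pair_rt = prior_pair[1];

  // generic component update: parameter theta with prior N(pm, pv), design
  // value xval[i] over affected subjects idx
  struct Updater {
    std::vector<double>& eta;
    const IntegerVector& y;
    CondLik& cl;
    bool conditional;
    std::vector<int>& setflag;
    int& flagtick;
    const IntegerVector& set0;

    bool update(double& theta, double pm, double pv, double sd,
                const std::vector<int>& idx, const double* xv,
                const int* xvi) {
      double d = R::rnorm(0.0, sd);
      double dll = 0.0;
      if (!conditional) {
        for (size_t t = 0; t < idx.size(); ++t) {
          int i = idx[t];
          double x = xv ? xv[t] : (xvi ? (double)xvi[t] : 1.0);
          dll += ll_term(y[i], eta[i] + d * x) - ll_term(y[i], eta[i]);
        }
      } else {
        // collect affected sets, tentatively shift psi, compare set lls
        ++flagtick;
        std::vector<int> touched;
        for (size_t t = 0; t < idx.size(); ++t) {
          int i = idx[t];
          double x = xv ? xv[t] : (xvi ? (double)xvi[t] : 1.0);
          eta[i] += d * x;
          int p = set0[i];
          if (setflag[p] != flagtick) { setflag[p] = flagtick; touched.push_back(p); }
        }
        for (size_t t = 0; t < touched.size(); ++t)
          dll += cl.set_value(eta, touched[t]) - cl.setll[touched[t]];
        // roll back; re-applied on acceptance
        for (size_t t = 0; t < idx.size(); ++t) {
          int i = idx[t];
          double x = xv ? xv[t] : (xvi ? (double)xvi[t] : 1.0);
          eta[i] -= d * x;
        }
      }
      double tn = theta + d;
      double dlp = -((tn - pm) * (tn - pm) - (theta - pm) * (theta - pm)) /
                   (2.0 * pv);
      bool acc = std::log(R::runif(0.0, 1.0)) < dll + dlp;
      if (acc) {
        theta = tn;
        for (size_t t = 0; t < idx.size(); ++t) {
          int i = idx[t];
          double x = xv ? xv[t] : (xvi ? (double)xvi[t] : 1.0);
          eta[i] += d * x;
        }
        if (conditional) {
          ++flagtick;
          for (size_t t = 0; t < idx.size(); ++t) {
            int p = set0[idx[t]];
            if (setflag[p] != flagtick) {
              setflag[p] = flagtick;
              cl.setll[p] = cl.set_value(eta, p);
            }
          }
        }
      }
      return acc;
    }
  } upd = {eta, y, cl, conditional, setflag, flagtick, set0};

  // per-component design-value caches (aligned with the index lists)
  std::vector<int> all_idx(n);
  for (int i = 0; i < n; ++i) all_idx[i] = i;
  std::vector<std::vector<std::vector<int> > > gc_xval(
      G, std::vector<std::vector<int> >(C));
  std::vector<std::vector<int> > g_xval(G);
  for (int g = 0; g < G; ++g) {
    for (int c = 0; c < C; ++c)
      for (size_t t = 0; t < gc_members[g][c].size(); ++t)
        gc_xval[g][c].push_back(S(gc_members[g][c][t], g));
    for (size_t t = 0; t < g_members[g].size(); ++t)
      g_xval[g].push_back(S(g_members[g][t], g));
  }
  std::vector<std::vector<double> > k_xval(K);
  for (int k = 0; k < K; ++k)
    for (size_t t = 0; t < k_members[k].size(); ++t)
      k_xval[k].push_back(Inter(k_members[k][t], k));
  std::vector<std::vector<double> > q_xval(Q, std::vector<double>(n));
  for (int q = 0; q < Q; ++q)
    for (int i = 0; i < n; ++i) q_xval[q][i] = X(i, q);

  // output layout
  int n_keep = n_iter / thin;
  int n_par = (conditional ? 0 : 1) + n_beta + (ge ? 2 * G : 0) + K + Q +
              (conditional ? 0 : C + P + 2);
  // columns: [alpha] beta(g,c) [mu tau2 if ge] gamma delta [a b var_area var_pair]
  NumericMatrix draws(n_keep, n_par);
  NumericVector deviance(n_keep);
  int row = 0;

  int total_iter = burn_in + n_iter;
  for (int t = 1; t <= total_iter; ++t) {
    if (t == burn_in + 1) ad.frozen = true;
    // --- Metropolis sweep ---
    if (!conditional) {
      bool acc = upd.update(alpha, 0.0, v0, ad.scale[0], all_idx, NULL, NULL);
      ad.record(0, acc);
    }
    if (ge) {
      for (int g = 0; g < G; ++g)
        for (int c = 0; c < C; ++c) {
          int j = off_beta + g * C + c;
          bool acc = upd.update(beta[g][c], mu[g], tau2[g], ad.scale[j],
                                gc_members[g][c], NULL,
                                gc_xval[g][c].empty() ? NULL : &gc_xval[g][c][0]);
          ad.record(j, acc);
        }
    } else {
      for (int g = 0; g < G; ++g) {
        int j = off_beta + g;
        bool acc = upd.update(mu[g], 0.0, v0, ad.scale[j], g_members[g], NULL,
                              g_xval[g].empty() ? NULL : &g_xval[g][0]);
        ad.record(j, acc);
      }
    }
    for (int k = 0; k < K; ++k) {
      int j = off_gam + k;
      bool acc = upd.update(gam[k], 0.0, v0, ad.scale[j], k_members[k],
                            k_xval[k].empty() ? NULL : &k_xval[k][0], NULL);
      ad.record(j, acc);
    }
    for (int q = 0; q < Q; ++q) {
      int j = off_del + q;
      bool acc = upd.update(del[q], 0.0, v0, ad.scale[j], all_idx,
                            &q_xval[q][0], NULL);
      ad.record(j, acc);
    }
    if (!conditional) {
      for (int c = 0; c < C; ++c) {
        int j = off_a + c;
        bool acc = upd.update(a[c], 0.0, var_area, ad.scale[j],
                              cat_members[c], NULL, NULL);
        ad.record(j, acc);
      }
      for (int p = 0; p < P; ++p) {
        int j = off_b + p;
        bool acc = upd.update(b[p], 0.0, var_pair, ad.scale[j],
                              set_members[p], NULL, NULL);
        ad.record(j, acc);
      }
    }
    // --- Gibbs sweep ---
    if (ge) {
      for (int g = 0; g < G; ++g) {
        // mu_g | beta_g. ~ normal-normal conjugate
        double prec = C / tau2[g] + 1.0 / v0;
        double sum_b = 0.0;
        for (int c = 0; c < C; ++c) sum_b += beta[g][c];
        double mean = (sum_b / tau2[g]) / prec;
        mu[g] = R::rnorm(mean, std::sqrt(1.0 / prec));
        // 1/tau2_g | beta_g., mu_g ~ gamma
        double ss = 0.0;
        for (int c = 0; c < C; ++c)
          ss += (beta[g][c] - mu[g]) * (beta[g][c] - mu[g]);
        double precn = R::rgamma(tau_sh + C / 2.0, 1.0 / (tau_rt + ss / 2.0));
        tau2[g] = 1.0 / precn;
      }
    }
    if (!conditional) {
      double ssa = 0.0;
      for (int c = 0; c < C; ++c) ssa += a[c] * a[c];
      var_area = 1.0 / R::rgamma(area_sh + C / 2.0, 1.0 / (area_rt + ssa / 2.0));
      double ssb = 0.0;
      for (int p = 0; p < P; ++p) ssb += b[p] * b[p];
      var_pair = 1.0 / R::rgamma(pair_sh + P / 2.0, 1.0 / (pair_rt + ssb / 2.0));
    }
    // periodic refresh against floating drift
    if (t % 1000 == 0) {
      rebuild(eta, S, X, Inter, cat0, set0, conditional, ge, alpha, beta, mu,
              gam, del, a, b);
      if (conditional) cl.refresh(eta);
    }
    // --- retention ---
    if (t > burn_in && (t - burn_in) % thin == 0) {
      int col = 0;
      if (!conditional) draws(row, col++) = alpha;
      if (ge) {
        for (int g = 0; g < G; ++g)
          for (int c = 0; c < C; ++c) draws(row, col++) = beta[g][c];
        for (int g = 0; g < G; ++g) draws(row, col++) = mu[g];
        for (int g = 0; g < G; ++g) draws(row, col++) = tau2[g];
      } else {
        for (int g = 0; g < G; ++g) draws(row, col++) = mu[g];
      }
      for (int k = 0; k < K; ++k) draws(row, col++) = gam[k];
      for (int q = 0; q < Q; ++q) draws(row, col++) = del[q];
      if (!conditional) {
        for (int c = 0; c < C; ++c) draws(row, col++) = a[c];
        for (int p = 0; p < P; ++p) draws(row, col++) = b[p];
        draws(row, col++) = var_area;
        draws(row, col++) = var_pair;
      }
      double dev;
      if (conditional) {
        dev = -2.0 * cl.total();
      } else {
        double ll = 0.0;
        for (int i = 0; i < n; ++i) ll += ll_term(y[i], eta[i]);
        dev = -2.0 * ll;
      }
      deviance[row] = dev;
      ++row;
    }
  }

  NumericVector acc_rates(n_comp);
  for (int j = 0; j < n_comp; ++j)
    acc_rates[j] = ad.tot_n[j] > 0 ? (double)ad.tot_acc[j] / ad.tot_n[j]
                                   : NA_REAL;
  NumericVector scales(n_comp);
  for (int j = 0; j < n_comp; ++j) scales[j] = ad.scale[j];

  return List::create(_["draws"] = draws, _["deviance"] = deviance,
                      _["accept"] = acc_rates, _["scales"] = scales);
}
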
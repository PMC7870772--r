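// Adaptive Metropolis-within-Gibbs sampler for the hierarchical diffusion
// model. Every scalar parameter gets a random-walk proposal whose step size
// is adapted toward a 0.44 acceptance rate during burn-in and frozen
// afterwards. The g-prior scale is updated by a conjugate inverse-gamma
// Gibbs step. All randomness goes through R's RNG, so chains are
// reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include "wiener_fpt.h"
using namespace Rcpp;

namespace {

struct Bounds { double lo, hi; };

// log density of a truncated normal (normalisation included: the group
// means and SDs enter it, so it cannot be dropped in hyper updates)
inline double ltnorm(double x, double m, double s, const Bounds& b) {
  if (x < b.lo || x > b.hi || s <= 0.0) return R_NegInf;
  double Z = R::pnorm(b.hi, m, s, 1, 0) - R::pnorm(b.lo, m, s, 1, 0);
  if (Z <= 0.0) return R_NegInf;
  return R::dnorm(x, m, s, 1) - std::log(Z);
}

inline double lhalfnorm(double x, double scale) {
  if (x <= 0.0) return R_NegInf;
  return R::dnorm(x, 0.0, scale, 1); // + log(2), constant
}

struct Adapt {
  double ls;      // log step size
  int n_acc, n_try;
  Adapt() : ls(-1.0), n_acc(0), n_try(0) {}
};

class Sampler {
public:
  // data
  std::vector<double> rt, sign;
  std::vector<int> upper, pidx, cidx; // 0-based indices
  int P, k, Jd, Ja, Jt, N;
  NumericMatrix Q, Zd, Za, Zt;
  // priors
  double pm_a, ps_a, pm_b, ps_b, pm_t, ps_t, pm_d, ps_d;
  double hs_a, hs_b, hs_t, hs_e, sd_theta;
  Bounds ba_, bb_, bt_, bd_;
  // state
  std::vector<double> a, b, t, d;       // participant-level (d: P*k, col-major)
  double mu_a, sg_a, mu_b, sg_b, mu_t, sg_t, mu_d, sg_e, g;
  std::vector<double> theta, bd_w, ba_w, bt_w;
  std::vector<double> qtheta, xd, xa, xt;
  std::vector<double> ll_pc;            // cached loglik per (p, c)
  std::vector<std::vector<int> > trials_pc; // trial ids per (p, c)
  std::vector<double> minrt;
  // adaptation (one per scalar parameter)
  std::vector<Adapt> ad_a, ad_b, ad_t, ad_d;
  Adapt ad_mu_a, ad_sg_a, ad_mu_b, ad_sg_b, ad_mu_t, ad_sg_t,
        ad_mu_d, ad_sg_e;
  std::vector<Adapt> ad_theta, ad_bdw, ad_baw, ad_btw;

  double trial_ll(int i, double ap, double bp, double tp) const {
    double v = sign[i] * d[pidx[i] + P * cidx[i]];
    return hbddm::ldwiener_trial(rt[i], upper[i], ap, bp, tp, v);
  }

  // loglik of cell (p, c) at given participant params and drift value
  double cell_ll(int p, int c, double ap, double bp, double tp,
                 double dpc) const {
    double s = 0.0;
    const std::vector<int>& tr = trials_pc[p + P * c];
    for (size_t j = 0; j < tr.size(); ++j) {
      int i = tr[j];
      s += hbddm::ldwiener_trial(rt[i], upper[i], ap, bp, tp,
                                 sign[i] * dpc);
      if (!R_FINITE(s)) return R_NegInf;
    }
    return s;
  }

  void refresh_lin_pred() {
    for (int c = 0; c < k; ++c) {
      double q = 0.0;
      for (int j = 0; j < k - 1; ++j) q += Q(c, j) * theta[j];
      qtheta[c] = q;
    }
    for (int p = 0; p < P; ++p) {
      double s = 0.0;
      for (int j = 0; j < Jd; ++j) s += Zd(p, j) * bd_w[j];
      xd[p] = s;
      s = 0.0;
      for (int j = 0; j < Ja; ++j) s += Za(p, j) * ba_w[j];
      xa[p] = s;
      s = 0.0;
      for (int j = 0; j < Jt; ++j) s += Zt(p, j) * bt_w[j];
      xt[p] = s;
    }
  }

  // truncated-normal prior terms of the participant-level parameters
  double lp_a(int p, double x) const {
    return ltnorm(x, mu_a + sg_a * xa[p], sg_a, ba_);
  }
  double lp_b(int p, double x) const { return ltnorm(x, mu_b, sg_b, bb_); }
  double lp_t(int p, double x) const {
    return ltnorm(x, mu_t + sg_t * xt[p], sg_t, bt_);
  }
  double lp_d(int p, int c, double x) const {
    return ltnorm(x, mu_d + sg_e * (qtheta[c] + xd[p]), sg_e, bd_);
  }

  double sum_lp_d_all() const {
    double s = 0.0;
    for (int p = 0; p < P; ++p)
      for (int c = 0; c < k; ++c) {
        s += lp_d(p, c, d[p + P * c]);
        if (!R_FINITE(s)) return R_NegInf;
      }
    return s;
  }

  void mh_step(double& x, Adapt& ad, double lp_cur, double lp_prop,
               double prop) {
    ad.n_try++;
    if (R_FINITE(lp_prop) &&
        std::log(unif_rand()) < lp_prop - lp_cur) {
      x = prop;
      ad.n_acc++;
    }
  }

  void adapt(Adapt& ad, int batch_no) {
    if (ad.n_try == 0) return;
    double rate = (double)ad.n_acc / ad.n_try;
    double delta = std::min(0.05, 1.0 / std::sqrt((double)batch_no));
    ad.ls += (rate > 0.44 ? delta : -delta);
    ad.ls = std::min(std::max(ad.ls, -12.0), 4.0);
    ad.n_acc = ad.n_try = 0;
  }
};

} // namespace

// [[Rcpp::export(name = ".hbm_sample_chain_cpp")]]
List hbm_sample_chain_cpp(NumericVector rt, IntegerVector upper,
                          NumericVector sign_, IntegerVector p_idx,
                          IntegerVector c_idx, int P, int k,
                          NumericMatrix Q, NumericMatrix Zd,
                          NumericMatrix Za, NumericMatrix Zt,
                          List priors, NumericVector bounds,
                          int n_samples, int n_burnin, int thin) {
  RNGScope scope;
  Sampler S;
  S.N = rt.size();
  S.rt.assign(rt.begin(), rt.end());
  S.sign.assign(sign_.begin(), sign_.end());
  S.upper.assign(upper.begin(), upper.end());
  S.P = P; S.k = k;
  S.Q = Q; S.Zd = Zd; S.Za = Za; S.Zt = Zt;
  S.Jd = Zd.ncol(); S.Ja = Za.ncol(); S.Jt = Zt.ncol();
  S.pidx.resize(S.N); S.cidx.resize(S.N);
  for (int i = 0; i < S.N; ++i) {
    S.pidx[i] = p_idx[i] - 1;
    S.cidx[i] = c_idx[i] - 1;
  }
  // bounds vector: alpha lo/hi, beta lo/hi, tau lo/hi, delta lo/hi
  S.ba_ = Bounds{bounds[0], bounds[1]};
  S.bb_ = Bounds{bounds[2], bounds[3]};
  S.bt_ = Bounds{bounds[4], bounds[5]};
  S.bd_ = Bounds{bounds[6], bounds[7]};
  NumericVector pa = priors["mu_alpha_prior"], pb = priors["mu_beta_prior"],
                pt = priors["mu_tau_prior"], pd = priors["mu_delta_prior"];
  S.pm_a = pa[0]; S.ps_a = pa[1];
  S.pm_b = pb[0]; S.ps_b = pb[1];
  S.pm_t = pt[0]; S.ps_t = pt[1];
  S.pm_d = pd[0]; S.ps_d = pd[1];
  S.hs_a = priors["sigma_alpha_scale"];
  S.hs_b = priors["sigma_beta_scale"];
  S.hs_t = priors["sigma_tau_scale"];
  S.hs_e = priors["sigma_eps_scale"];
  S.sd_theta = priors["theta_prior_sd"];

  // trial grouping and minimum RT per participant
  S.trials_pc.resize(P * k);
  S.minrt.assign(P, R_PosInf);
  for (int i = 0; i < S.N; ++i) {
    S.trials_pc[S.pidx[i] + P * S.cidx[i]].push_back(i);
    if (S.rt[i] < S.minrt[S.pidx[i]]) S.minrt[S.pidx[i]] = S.rt[i];
  }

  // starting values: uniform over admissible ranges
  S.a.resize(P); S.b.resize(P); S.t.resize(P); S.d.resize(P * k);
  for (int p = 0; p < P; ++p) {
    S.a[p] = R::runif(0.6, 2.5);
    S.b[p] = R::runif(0.40, 0.60);
    double hi_t = std::min(0.9 * S.minrt[p], S.bt_.hi);
    S.t[p] = (hi_t > S.bt_.lo + 1e-3)
               ? R::runif(S.bt_.lo, hi_t)
               : S.bt_.lo + 1e-4;
    for (int c = 0; c < k; ++c) S.d[p + P * c] = R::runif(0.5, 4.0);
  }
  S.mu_a = R::runif(0.8, 2.0); S.sg_a = R::runif(0.1, 0.8);
  S.mu_b = R::runif(0.45, 0.55); S.sg_b = R::runif(0.02, 0.15);
  S.mu_t = R::runif(0.2, 0.6); S.sg_t = R::runif(0.03, 0.25);
  S.mu_d = R::runif(1.0, 3.5); S.sg_e = R::runif(0.4, 1.2);
  S.theta.assign(k - 1, 0.0);
  for (int j = 0; j < k - 1; ++j) S.theta[j] = R::runif(-0.5, 0.5);
  S.bd_w.assign(S.Jd, 0.0); S.ba_w.assign(S.Ja, 0.0);
  S.bt_w.assign(S.Jt, 0.0);
  for (int j = 0; j < S.Jd; ++j) S.bd_w[j] = R::runif(-0.3, 0.3);
  for (int j = 0; j < S.Ja; ++j) S.ba_w[j] = R::runif(-0.3, 0.3);
  for (int j = 0; j < S.Jt; ++j) S.bt_w[j] = R::runif(-0.3, 0.3);
  S.g = 1.0;
  S.qtheta.resize(k); S.xd.resize(P); S.xa.resize(P); S.xt.resize(P);
  S.refresh_lin_pred();

  // cached likelihoods
  S.ll_pc.assign(P * k, 0.0);
  for (int p = 0; p < P; ++p)
    for (int c = 0; c < k; ++c)
      S.ll_pc[p + P * c] =
        S.cell_ll(p, c, S.a[p], S.b[p], S.t[p], S.d[p + P * c]);

  // adaptation records
  S.ad_a.assign(P, Adapt()); S.ad_b.assign(P, Adapt());
  S.ad_t.assign(P, Adapt()); S.ad_d.assign(P * k, Adapt());
  S.ad_theta.assign(k - 1, Adapt());
  S.ad_bdw.assign(S.Jd, Adapt()); S.ad_baw.assign(S.Ja, Adapt());
  S.ad_btw.assign(S.Jt, Adapt());
  // participant-level steps start smaller than hyper steps
  for (int p = 0; p < P; ++p) {
    S.ad_a[p].ls = std::log(0.15); S.ad_b[p].ls = std::log(0.05);
    S.ad_t[p].ls = std::log(0.05);
  }
  for (int i = 0; i < P * k; ++i) S.ad_d[i].ls = std::log(0.3);

  int n_retain = (n_samples - n_burnin) / thin;
  int npar = 8 + (k - 1) + S.Jd + S.Ja + S.Jt + 1 + 3 * P + P * k;
  NumericMatrix draws(n_retain, npar);
  NumericVector deviance(n_retain);
  int row = 0, J_all = S.Jd + S.Ja + S.Jt;

  for (int iter = 1; iter <= n_samples; ++iter) {
    bool adapting = iter <= n_burnin;

    // --- participant-level updates ---
    for (int p = 0; p < P; ++p) {
      // alpha_p
      {
        double prop = S.a[p] + std::exp(S.ad_a[p].ls) * norm_rand();
        double lp_cur = S.lp_a(p, S.a[p]);
        double lp_prop = S.lp_a(p, prop);
        if (R_FINITE(lp_prop)) {
          double llc = 0.0, llp = 0.0;
          std::vector<double> newll(k);
          for (int c = 0; c < k; ++c) {
            llc += S.ll_pc[p + P * c];
            newll[c] = S.cell_ll(p, c, prop, S.b[p], S.t[p], S.d[p + P * c]);
            llp += newll[c];
          }
          S.ad_a[p].n_try++;
          if (R_FINITE(llp) &&
              std::log(unif_rand()) < (llp + lp_prop) - (llc + lp_cur)) {
            S.a[p] = prop;
            for (int c = 0; c < k; ++c) S.ll_pc[p + P * c] = newll[c];
            S.ad_a[p].n_acc++;
          }
        } else S.ad_a[p].n_try++;
      }
      // beta_p
      {
        double prop = S.b[p] + std::exp(S.ad_b[p].ls) * norm_rand();
        double lp_cur = S.lp_b(p, S.b[p]);
        double lp_prop = S.lp_b(p, prop);
        if (R_FINITE(lp_prop)) {
          double llc = 0.0, llp = 0.0;
          std::vector<double> newll(k);
          for (int c = 0; c < k; ++c) {
            llc += S.ll_pc[p + P * c];
            newll[c] = S.cell_ll(p, c, S.a[p], prop, S.t[p], S.d[p + P * c]);
            llp += newll[c];
          }
          S.ad_b[p].n_try++;
          if (R_FINITE(llp) &&
              std::log(unif_rand()) < (llp + lp_prop) - (llc + lp_cur)) {
            S.b[p] = prop;
            for (int c = 0; c < k; ++c) S.ll_pc[p + P * c] = newll[c];
            S.ad_b[p].n_acc++;
          }
        } else S.ad_b[p].n_try++;
      }
      // tau_p
      {
        double prop = S.t[p] + std::exp(S.ad_t[p].ls) * norm_rand();
        double lp_cur = S.lp_t(p, S.t[p]);
        double lp_prop = (prop < S.minrt[p]) ? S.lp_t(p, prop) : R_NegInf;
        if (R_FINITE(lp_prop)) {
          double llc = 0.0, llp = 0.0;
          std::vector<double> newll(k);
          for (int c = 0; c < k; ++c) {
            llc += S.ll_pc[p + P * c];
            newll[c] = S.cell_ll(p, c, S.a[p], S.b[p], prop, S.d[p + P * c]);
            llp += newll[c];
          }
          S.ad_t[p].n_try++;
          if (R_FINITE(llp) &&
              std::log(unif_rand()) < (llp + lp_prop) - (llc + lp_cur)) {
            S.t[p] = prop;
            for (int c = 0; c < k; ++c) S.ll_pc[p + P * c] = newll[c];
            S.ad_t[p].n_acc++;
          }
        } else S.ad_t[p].n_try++;
      }
      // delta_pc
      for (int c = 0; c < k; ++c) {
        int id = p + P * c;
        double prop = S.d[id] + std::exp(S.ad_d[id].ls) * norm_rand();
        double lp_cur = S.lp_d(p, c, S.d[id]);
        double lp_prop = S.lp_d(p, c, prop);
        S.ad_d[id].n_try++;
        if (R_FINITE(lp_prop)) {
          double llp = S.cell_ll(p, c, S.a[p], S.b[p], S.t[p], prop);
          if (R_FINITE(llp) &&
              std::log(unif_rand()) <
                (llp + lp_prop) - (S.ll_pc[id] + lp_cur)) {
            S.d[id] = prop;
            S.ll_pc[id] = llp;
            S.ad_d[id].n_acc++;
          }
        }
      }
    }

    // --- hyperparameter updates (prior-level only, no trial likelihood) ---
    // mu_alpha
    {
      double prop = S.mu_a + std::exp(S.ad_mu_a.ls) * norm_rand();
      double cur = ltnorm(S.mu_a, S.pm_a, S.ps_a, S.ba_),
             prp = ltnorm(prop, S.pm_a, S.ps_a, S.ba_);
      if (R_FINITE(prp)) {
        double save = S.mu_a;
        for (int p = 0; p < P; ++p) cur += S.lp_a(p, S.a[p]);
        S.mu_a = prop;
        for (int p = 0; p < P; ++p) prp += S.lp_a(p, S.a[p]);
        S.mu_a = save;
        S.mh_step(S.mu_a, S.ad_mu_a, cur, prp, prop);
      } else S.ad_mu_a.n_try++;
    }
    // sigma_alpha (log-scale walk, Jacobian included)
    {
      double prop = S.sg_a * std::exp(std::exp(S.ad_sg_a.ls) * norm_rand());
      double cur = lhalfnorm(S.sg_a, S.hs_a) + std::log(S.sg_a),
             prp = lhalfnorm(prop, S.hs_a) + std::log(prop);
      double save = S.sg_a;
      for (int p = 0; p < P; ++p) cur += S.lp_a(p, S.a[p]);
      S.sg_a = prop;
      for (int p = 0; p < P; ++p) prp += S.lp_a(p, S.a[p]);
      S.sg_a = save;
      S.mh_step(S.sg_a, S.ad_sg_a, cur, prp, prop);
    }
    // mu_beta / sigma_beta
    {
      double prop = S.mu_b + std::exp(S.ad_mu_b.ls) * norm_rand();
      double cur = ltnorm(S.mu_b, S.pm_b, S.ps_b, S.bb_),
             prp = ltnorm(prop, S.pm_b, S.ps_b, S.bb_);
      if (R_FINITE(prp)) {
        double save = S.mu_b;
        for (int p = 0; p < P; ++p) cur += S.lp_b(p, S.b[p]);
        S.mu_b = prop;
        for (int p = 0; p < P; ++p) prp += S.lp_b(p, S.b[p]);
        S.mu_b = save;
        S.mh_step(S.mu_b, S.ad_mu_b, cur, prp, prop);
      } else S.ad_mu_b.n_try++;
    }
    {
      double prop = S.sg_b * std::exp(std::exp(S.ad_sg_b.ls) * norm_rand());
      double cur = lhalfnorm(S.sg_b, S.hs_b) + std::log(S.sg_b),
             prp = lhalfnorm(prop, S.hs_b) + std::log(prop);
      double save = S.sg_b;
      for (int p = 0; p < P; ++p) cur += S.lp_b(p, S.b[p]);
      S.sg_b = prop;
      for (int p = 0; p < P; ++p) prp += S.lp_b(p, S.b[p]);
      S.sg_b = save;
      S.mh_step(S.sg_b, S.ad_sg_b, cur, prp, prop);
    }
    // mu_tau / sigma_tau
    {
      double prop = S.mu_t + std::exp(S.ad_mu_t.ls) * norm_rand();
      double cur = ltnorm(S.mu_t, S.pm_t, S.ps_t, S.bt_),
             prp = ltnorm(prop, S.pm_t, S.ps_t, S.bt_);
      if (R_FINITE(prp)) {
        double save = S.mu_t;
        for (int p = 0; p < P; ++p) cur += S.lp_t(p, S.t[p]);
        S.mu_t = prop;
        for (int p = 0; p < P; ++p) prp += S.lp_t(p, S.t[p]);
        S.mu_t = save;
        S.mh_step(S.mu_t, S.ad_mu_t, cur, prp, prop);
      } else S.ad_mu_t.n_try++;
    }
    {
      double prop = S.sg_t * std::exp(std::exp(S.ad_sg_t.ls) * norm_rand());
      double cur = lhalfnorm(S.sg_t, S.hs_t) + std::log(S.sg_t),
             prp = lhalfnorm(prop, S.hs_t) + std::log(prop);
      double save = S.sg_t;
      for (int p = 0; p < P; ++p) cur += S.lp_t(p, S.t[p]);
      S.sg_t = prop;
      for (int p = 0; p < P; ++p) prp += S.lp_t(p, S.t[p]);
      S.sg_t = save;
      S.mh_step(S.sg_t, S.ad_sg_t, cur, prp, prop);
    }
    // mu_delta / sigma_eps
    {
      double prop = S.mu_d + std::exp(S.ad_mu_d.ls) * norm_rand();
      double cur = ltnorm(S.mu_d, S.pm_d, S.ps_d, S.bd_),
             prp = ltnorm(prop, S.pm_d, S.ps_d, S.bd_);
      if (R_FINITE(prp)) {
        double save = S.mu_d;
        cur += S.sum_lp_d_all();
        S.mu_d = prop;
        prp += S.sum_lp_d_all();
        S.mu_d = save;
        S.mh_step(S.mu_d, S.ad_mu_d, cur, prp, prop);
      } else S.ad_mu_d.n_try++;
    }
    {
      double prop = S.sg_e * std::exp(std::exp(S.ad_sg_e.ls) * norm_rand());
      double cur = lhalfnorm(S.sg_e, S.hs_e) + std::log(S.sg_e),
             prp = lhalfnorm(prop, S.hs_e) + std::log(prop);
      double save = S.sg_e;
      cur += S.sum_lp_d_all();
      S.sg_e = prop;
      prp += S.sum_lp_d_all();
      S.sg_e = save;
      S.mh_step(S.sg_e, S.ad_sg_e, cur, prp, prop);
    }
    // theta
    for (int j = 0; j < k - 1; ++j) {
      double prop = S.theta[j] + std::exp(S.ad_theta[j].ls) * norm_rand();
      double cur = R::dnorm(S.theta[j], 0.0, S.sd_theta, 1),
             prp = R::dnorm(prop, 0.0, S.sd_theta, 1);
      double save = S.theta[j];
      cur += S.sum_lp_d_all();
      S.theta[j] = prop;
      S.refresh_lin_pred();
      prp += S.sum_lp_d_all();
      S.ad_theta[j].n_try++;
      if (R_FINITE(prp) && std::log(unif_rand()) < prp - cur) {
        S.ad_theta[j].n_acc++;
      } else {
        S.theta[j] = save;
        S.refresh_lin_pred();
      }
    }
    // regression weights
    double g_sd = std::sqrt(S.g);
    for (int j = 0; j < S.Jd; ++j) {
      double prop = S.bd_w[j] + std::exp(S.ad_bdw[j].ls) * norm_rand();
      double cur = R::dnorm(S.bd_w[j], 0.0, g_sd, 1),
             prp = R::dnorm(prop, 0.0, g_sd, 1);
      double save = S.bd_w[j];
      cur += S.sum_lp_d_all();
      S.bd_w[j] = prop;
      S.refresh_lin_pred();
      prp += S.sum_lp_d_all();
      S.ad_bdw[j].n_try++;
      if (R_FINITE(prp) && std::log(unif_rand()) < prp - cur) {
        S.ad_bdw[j].n_acc++;
      } else {
        S.bd_w[j] = save;
        S.refresh_lin_pred();
      }
    }
    for (int j = 0; j < S.Ja; ++j) {
      double prop = S.ba_w[j] + std::exp(S.ad_baw[j].ls) * norm_rand();
      double cur = R::dnorm(S.ba_w[j], 0.0, g_sd, 1),
             prp = R::dnorm(prop, 0.0, g_sd, 1);
      double save = S.ba_w[j];
      for (int p = 0; p < P; ++p) cur += S.lp_a(p, S.a[p]);
      S.ba_w[j] = prop;
      S.refresh_lin_pred();
      for (int p = 0; p < P; ++p) prp += S.lp_a(p, S.a[p]);
      S.ad_baw[j].n_try++;
      if (R_FINITE(prp) && std::log(unif_rand()) < prp - cur) {
        S.ad_baw[j].n_acc++;
      } else {
        S.ba_w[j] = save;
        S.refresh_lin_pred();
      }
    }
    for (int j = 0; j < S.Jt; ++j) {
      double prop = S.bt_w[j] + std::exp(S.ad_btw[j].ls) * norm_rand();
      double cur = R::dnorm(S.bt_w[j], 0.0, g_sd, 1),
             prp = R::dnorm(prop, 0.0, g_sd, 1);
      double save = S.bt_w[j];
      for (int p = 0; p < P; ++p) cur += S.lp_t(p, S.t[p]);
      S.bt_w[j] = prop;
      S.refresh_lin_pred();
      for (int p = 0; p < P; ++p) prp += S.lp_t(p, S.t[p]);
      S.ad_btw[j].n_try++;
      if (R_FINITE(prp) && std::log(unif_rand()) < prp - cur) {
        S.ad_btw[j].n_acc++;
      } else {
        S.bt_w[j] = save;
        S.refresh_lin_pred();
      }
    }
    // g: conjugate inverse-gamma update
    if (J_all > 0) {
      double ssq = 0.0;
      for (int j = 0; j < S.Jd; ++j) ssq += S.bd_w[j] * S.bd_w[j];
      for (int j = 0; j < S.Ja; ++j) ssq += S.ba_w[j] * S.ba_w[j];
      for (int j = 0; j < S.Jt; ++j) ssq += S.bt_w[j] * S.bt_w[j];
      S.g = 1.0 / R::rgamma(0.5 + 0.5 * J_all, 1.0 / (0.5 + 0.5 * ssq));
    }

    // --- adaptation ---
    if (adapting && iter % 50 == 0) {
      int batch = iter / 50;
      for (int p = 0; p < P; ++p) {
        S.adapt(S.ad_a[p], batch); S.adapt(S.ad_b[p], batch);
        S.adapt(S.ad_t[p], batch);
      }
      for (int i = 0; i < P * k; ++i) S.adapt(S.ad_d[i], batch);
      S.adapt(S.ad_mu_a, batch); S.adapt(S.ad_sg_a, batch);
      S.adapt(S.ad_mu_b, batch); S.adapt(S.ad_sg_b, batch);
      S.adapt(S.ad_mu_t, batch); S.adapt(S.ad_sg_t, batch);
      S.adapt(S.ad_mu_d, batch); S.adapt(S.ad_sg_e, batch);
      for (int j = 0; j < k - 1; ++j) S.adapt(S.ad_theta[j], batch);
      for (int j = 0; j < S.Jd; ++j) S.adapt(S.ad_bdw[j], batch);
      for (int j = 0; j < S.Ja; ++j) S.adapt(S.ad_baw[j], batch);
      for (int j = 0; j < S.Jt; ++j) S.adapt(S.ad_btw[j], batch);
    }

    // --- retain draw ---
    if (iter > n_burnin && (iter - n_burnin) % thin == 0) {
      double dev = 0.0;
      for (int i = 0; i < P * k; ++i) dev += S.ll_pc[i];
      if (!R_FINITE(dev))
        stop("non-finite likelihood at retained draw %d", row + 1);
      deviance[row] = -2.0 * dev;
      int col = 0;
      draws(row, col++) = S.mu_a; draws(row, col++) = S.sg_a;
      draws(row, col++) = S.mu_b; draws(row, col++) = S.sg_b;
      draws(row, col++) = S.mu_t; draws(row, col++) = S.sg_t;
      draws(row, col++) = S.mu_d; draws(row, col++) = S.sg_e;
      for (int j = 0; j < k - 1; ++j) draws(row, col++) = S.theta[j];
      for (int j = 0; j < S.Jd; ++j) draws(row, col++) = S.bd_w[j];
      for (int j = 0; j < S.Ja; ++j) draws(row, col++) = S.ba_w[j];
      for (int j = 0; j < S.Jt; ++j) draws(row, col++) = S.bt_w[j];
      draws(row, col++) = S.g;
      for (int p = 0; p < P; ++p) draws(row, col++) = S.a[p];
      for (int p = 0; p < P; ++p) draws(row, col++) = S.b[p];
      for (int p = 0; p < P; ++p) draws(row, col++) = S.t[p];
      for (int i = 0; i < P * k; ++i) draws(row, col++) = S.d[i];
      ++row;
    }
    if (iter % 500 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["draws"] = draws, _["deviance"] = deviance);
}

// deviance at supplied participant-level parameters (DIC plug-in)
// [[Rcpp::export(name = ".hbm_deviance_cpp")]]
double hbm_deviance_cpp(NumericVector rt, IntegerVector upper,
                        NumericVector sign_, IntegerVector p_idx,
                        IntegerVector c_idx, NumericVector alpha,
                        NumericVector beta, NumericVector tau,
                        NumericMatrix delta) {
  int N = rt.size(), P = alpha.size();
  double ll = 0.0;
  for (int i = 0; i < N; ++i) {
    int p = p_idx[i] - 1, c = c_idx[i] - 1;
    ll += hbddm::ldwiener_trial(rt[i], upper[i], alpha[p], beta[p], tau[p],
                                sign_[i] * delta(p, c));
  }
  (void)P;
  return -2.0 * ll;
}

// generic adaptive random-walk MH on a scalar, driven by an R log-posterior
// function: used to validate the MH kernel against conjugate cases.
// [[Rcpp::export(name = ".amwg_chain_cpp")]]
NumericVector amwg_chain_cpp(Function logpost, double init, int n_samples,
                             int n_burnin) {
  RNGScope scope;
  NumericVector out(n_samples - n_burnin);
  double x = init, lp = as<double>(logpost(x));
  Adapt ad;
  for (int iter = 1; iter <= n_samples; ++iter) {
    double prop = x + std::exp(ad.ls) * norm_rand();
    double lpp = as<double>(logpost(prop));
    ad.n_try++;
    if (R_FINITE(lpp) && std::log(unif_rand()) < lpp - lp) {
      x = prop; lp = lpp; ad.n_acc++;
    }
    if (iter <= n_burnin && iter % 50 == 0) {
      double rate = (double)ad.n_acc / ad.n_try;
      double delta = std::min(0.05, 1.0 / std::sqrt(iter / 50.0));
      ad.ls += (rate > 0.44 ? delta : -delta);
      ad.n_acc = ad.n_try = 0;
    }
    if (iter > n_burnin) out[iter - n_burnin - 1] = x;
  }
  return out;
}
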
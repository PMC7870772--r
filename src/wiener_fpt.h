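// Shared Wiener first-passage-time density (lower boundary), used by both
// the exported density/likelihood functions and the MCMC sampler.
#ifndef HBDDM_WIENER_FPT_H
#define HBDDM_WIENER_FPT_H

#include <cmath>
#include <R.h>
#include <Rmath.h>

namespace hbddm {

const double kTermTol = 1e-29; // absolute tolerance on series terms

// scaled density f(tt | v=0, a=1, w) for the LOWER boundary, tt = t / a^2.
// method: 0 auto (fewer-terms expansion), 1 force small-time, 2 force large.
inline double wfpt_scaled(double tt, double w, int method) {
  if (!R_FINITE(tt) || tt <= 0.0) return 0.0;
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * kTermTol < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt *
                         std::log(2.0 * kTermTol * std::sqrt(2.0 * M_PI * tt)));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * tt * kTermTol < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * kTermTol) /
                   (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  bool use_small = (method == 1) || (method == 0 && ks < kl);
  double p = 0.0;
  if (use_small) {
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; ++k) {
      double z = w + 2.0 * k;
      p += z * std::exp(-z * z / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
           std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p;
}

// density of hitting the LOWER boundary at decision time t (= rt - tau)
inline double dwiener_lower(double t, double a, double w, double v,
                            int method) {
  if (t <= 0.0) return 0.0;
  double tt = t / (a * a);
  double p = wfpt_scaled(tt, w, method);
  double dens = p * std::exp(-v * a * w - v * v * t / 2.0) / (a * a);
  return dens < 0.0 ? 0.0 : dens;
}

// log density for one trial: rt, response boundary (1 = upper) and SIGNED
// drift v (already sign-flipped for stimulus direction)
inline double ldwiener_trial(double rt, int upper, double a, double w,
                             double tau, double v) {
  double t_dec = rt - tau;
  if (t_dec <= 0.0) return R_NegInf;
  double ww = upper ? 1.0 - w : w;
  double vv = upper ? -v : v;
  double dens = dwiener_lower(t_dec, a, ww, vv, 0);
  if (dens <= 0.0) return R_NegInf;
  return std::log(dens);
}

} // namespace hbddm

#endif
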
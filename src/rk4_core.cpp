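// Fixed-step RK4 integration of a delay-coupled cluster of three-population
// neural masses.  Delayed node outputs dy_j = ye_j - yi_j are read from the
// recorded trajectory at an integer step delay and held constant across the
// four stage evaluations of a step (delays are long relative to dt, so
// stage-level interpolation error is negligible).  Noise and stimulus are
// sampled per step, not per stage.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Transfer {
  int variant;   // 0 none, 1 erfc, 2 sigmoid, 3 sigmoid_weighted
  int argform;   // 0: v/v0 - wav, 1: v0*v - wav, 2: wav - v0/v (ratio form)
  double qm, v0, r, wav;
};

static inline double transfer(double v, const Transfer& tp) {
  switch (tp.variant) {
  case 0: return 0.0;
  case 2: return 2.0 * tp.qm / (1.0 + std::exp(tp.r * (tp.v0 - v)));
  default: {
    if (v <= 0.0 && (tp.argform == 2 || tp.variant == 1))
      return 0.0;                      // rates are non-negative
    double x = (tp.argform == 0)   ? v / tp.v0 - tp.wav
               : (tp.argform == 1) ? tp.v0 * v - tp.wav
                                   : tp.wav - tp.v0 / v;
    if (tp.variant == 3) return 2.0 * tp.qm / (1.0 + std::exp(-tp.r * x));
    return tp.qm * std::erfc(-tp.r * x);
  }
  }
}

// [[Rcpp::export(name = ".rk4_cluster_core")]]
List rk4_cluster_core(NumericVector state0, int nsteps, double dt,
                      NumericVector A, NumericVector B,
                      NumericVector C1, NumericVector C2,
                      NumericVector C3, NumericVector C4,
                      NumericVector tau_e, NumericVector tau_i,
                      IntegerVector int_variant, IntegerVector int_argform,
                      NumericVector int_qm, NumericVector int_v0,
                      NumericVector int_r, NumericVector int_wav,
                      IntegerVector out_variant, IntegerVector out_argform,
                      NumericVector out_qm, NumericVector out_v0,
                      NumericVector out_r, NumericVector out_wav,
                      NumericMatrix Wbar, IntegerMatrix dsteps,
                      NumericMatrix noise, NumericMatrix stim) {
  const int n = A.size();
  if (state0.size() != 6 * n) stop("state0 must have length 6*n");
  if (noise.nrow() != n || noise.ncol() < nsteps) stop("noise must be n x nsteps");
  if (stim.nrow() != n || stim.ncol() < nsteps) stop("stim must be n x nsteps");

  std::vector<Transfer> ti(n), to(n);
  for (int k = 0; k < n; ++k) {
    ti[k] = {int_variant[k], int_argform[k], int_qm[k], int_v0[k], int_r[k],
             int_wav[k]};
    to[k] = {out_variant[k], out_argform[k], out_qm[k], out_v0[k], out_r[k],
             out_wav[k]};
  }

  NumericMatrix Y0(n, nsteps + 1), Y0d(n, nsteps + 1);
  NumericMatrix Ye(n, nsteps + 1), Yed(n, nsteps + 1);
  NumericMatrix Yi(n, nsteps + 1), Yid(n, nsteps + 1);

  std::vector<double> y0(n), y0d(n), ye(n), yed(n), yi(n), yid(n);
  for (int k = 0; k < n; ++k) {
    y0[k] = state0[6 * k];     y0d[k] = state0[6 * k + 1];
    ye[k] = state0[6 * k + 2]; yed[k] = state0[6 * k + 3];
    yi[k] = state0[6 * k + 4]; yid[k] = state0[6 * k + 5];
    Y0(k, 0) = y0[k]; Y0d(k, 0) = y0d[k];
    Ye(k, 0) = ye[k]; Yed(k, 0) = yed[k];
    Yi(k, 0) = yi[k]; Yid(k, 0) = yid[k];
  }

  std::vector<double> drive_e(n);
  // stage work arrays (6 components per node)
  std::vector<double> s0(6 * n), k1(6 * n), k2(6 * n), k3(6 * n), k4(6 * n),
      tmp(6 * n);

  // derivative of the full cluster state, with per-step drive held fixed
  auto deriv = [&](const std::vector<double>& s, std::vector<double>& ds) {
    for (int k = 0; k < n; ++k) {
      const double te = tau_e[k], tii = tau_i[k];
      const double ae = A[k] / te, bi = B[k] / tii;
      const double vy0 = s[6 * k], vy0d = s[6 * k + 1];
      const double vye = s[6 * k + 2], vyed = s[6 * k + 3];
      const double vyi = s[6 * k + 4], vyid = s[6 * k + 5];
      ds[6 * k] = vy0d;
      ds[6 * k + 1] = ae * transfer(vye - vyi, ti[k]) - 2.0 / te * vy0d -
                      vy0 / (te * te);
      ds[6 * k + 2] = vyed;
      ds[6 * k + 3] = ae * C2[k] * transfer(C1[k] * vy0, ti[k]) + drive_e[k] -
                      2.0 / te * vyed - vye / (te * te);
      ds[6 * k + 4] = vyid;
      ds[6 * k + 5] = bi * C4[k] * transfer(C3[k] * vy0, ti[k]) -
                      2.0 / tii * vyid - vyi / (tii * tii);
    }
  };

  for (int i = 0; i < nsteps; ++i) {
    // per-step excitatory drive: noise + stimulus + delayed coupled input
    for (int k = 0; k < n; ++k) {
      double coupled = 0.0;
      for (int j = 0; j < n; ++j) {
        if (Wbar(k, j) == 0.0) continue;
        const int m = i - dsteps(k, j);
        const double dyj = (m >= 0) ? Ye(j, m) - Yi(j, m) : 0.0;
        coupled += Wbar(k, j) * transfer(dyj, to[j]);
      }
      drive_e[k] = (A[k] / tau_e[k]) * (noise(k, i) + stim(k, i) + coupled);
    }

    for (int k = 0; k < n; ++k) {
      s0[6 * k] = y0[k];     s0[6 * k + 1] = y0d[k];
      s0[6 * k + 2] = ye[k]; s0[6 * k + 3] = yed[k];
      s0[6 * k + 4] = yi[k]; s0[6 * k + 5] = yid[k];
    }
    deriv(s0, k1);
    for (int q = 0; q < 6 * n; ++q) tmp[q] = s0[q] + 0.5 * dt * k1[q];
    deriv(tmp, k2);
    for (int q = 0; q < 6 * n; ++q) tmp[q] = s0[q] + 0.5 * dt * k2[q];
    deriv(tmp, k3);
    for (int q = 0; q < 6 * n; ++q) tmp[q] = s0[q] + dt * k3[q];
    deriv(tmp, k4);
    for (int k = 0; k < n; ++k) {
      const int b = 6 * k;
      y0[k]  += dt / 6.0 * (k1[b] + 2 * k2[b] + 2 * k3[b] + k4[b]);
      y0d[k] += dt / 6.0 * (k1[b + 1] + 2 * k2[b + 1] + 2 * k3[b + 1] + k4[b + 1]);
      ye[k]  += dt / 6.0 * (k1[b + 2] + 2 * k2[b + 2] + 2 * k3[b + 2] + k4[b + 2]);
      yed[k] += dt / 6.0 * (k1[b + 3] + 2 * k2[b + 3] + 2 * k3[b + 3] + k4[b + 3]);
      yi[k]  += dt / 6.0 * (k1[b + 4] + 2 * k2[b + 4] + 2 * k3[b + 4] + k4[b + 4]);
      yid[k] += dt / 6.0 * (k1[b + 5] + 2 * k2[b + 5] + 2 * k3[b + 5] + k4[b + 5]);
      Y0(k, i + 1) = y0[k]; Y0d(k, i + 1) = y0d[k];
      Ye(k, i + 1) = ye[k]; Yed(k, i + 1) = yed[k];
      Yi(k, i + 1) = yi[k]; Yid(k, i + 1) = yid[k];
      if (!std::isfinite(y0[k]) || !std::isfinite(ye[k]) ||
          !std::isfinite(yi[k]))
        stop("state blow-up at step %d (t = %g s), node %d", i + 1,
             (i + 1) * dt, k + 1);
    }
  }

  return List::create(_["y0"] = Y0, _["y0d"] = Y0d, _["ye"] = Ye,
                      _["yed"] = Yed, _["yi"] = Yi, _["yid"] = Yid);
}
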
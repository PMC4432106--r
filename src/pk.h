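#ifndef TOXKINSIM_PK_H
#define TOXKINSIM_PK_H

#include <cmath>
#include <limits>
#include <vector>
#include <algorithm>
#include <stdexcept>

// Model codes shared with the R side:
//   0 = ETA_LINEAR (test harness: constant mean, additive random effect)
//   1 = ONE_CMT     params (KA, V, CL)
//   2 = ONE_CMT_MM  params (KA, V, VMAX, KM)
//   3 = TWO_CMT     params (KA, V, CL, K12, K21)

namespace tks {

struct Regimen {
  double dose;   // mg/kg per administration
  double tau;    // dosing interval, h
  int n_doses;   // number of administrations
  double start;  // time of first dose, h
};

// doses administered at or before time t
inline int doses_given(const Regimen& reg, double t) {
  if (reg.n_doses <= 0 || t < reg.start) return 0;
  int m = static_cast<int>(std::floor((t - reg.start) / reg.tau + 1e-12)) + 1;
  if (m > reg.n_doses) m = reg.n_doses;
  if (m < 0) m = 0;
  return m;
}

// sum_{k=0}^{m-1} exp(-lam * (s + k*tau)); all terms <= exp(-lam*s), stable.
inline double accum(double lam, double s, int m, double tau) {
  double x = std::exp(-lam * s);
  if (m <= 1) return x;
  double r = std::exp(-lam * tau);
  double denom = 1.0 - r;
  if (denom < 1e-14) return x * m;
  return x * (1.0 - std::exp(-lam * tau * m)) / denom;
}

// ---- one-compartment, first-order absorption and elimination ----

inline double conc_onecmt(double t, const Regimen& reg,
                          double KA, double V, double CL) {
  int m = doses_given(reg, t);
  if (m == 0 || reg.dose <= 0.0) return 0.0;
  double ke = CL / V;
  double s = t - reg.start - (m - 1) * reg.tau;
  if (std::fabs(KA - ke) < 1e-9 * ke) {
    // removable singularity: per-dose limit D*KA*u*exp(-KA*u)/V
    double sum = 0.0;
    for (int k = 0; k < m; ++k) {
      double u = s + k * reg.tau;
      sum += u * std::exp(-KA * u);
    }
    return reg.dose * KA / V * sum;
  }
  double c = reg.dose * KA / (V * (KA - ke)) *
             (accum(ke, s, m, reg.tau) - accum(KA, s, m, reg.tau));
  return c > 0.0 ? c : 0.0;
}

// cumulative AUC from time 0 to T
inline double cauc_onecmt(double T, const Regimen& reg,
                          double KA, double V, double CL) {
  int m = doses_given(reg, T);
  if (m == 0 || reg.dose <= 0.0) return 0.0;
  double ke = CL / V;
  double s = T - reg.start - (m - 1) * reg.tau;
  if (std::fabs(KA - ke) < 1e-9 * ke) {
    double sum = 0.0;
    for (int k = 0; k < m; ++k) {
      double u = s + k * reg.tau;
      sum += (1.0 - (1.0 + KA * u) * std::exp(-KA * u)) / KA;
    }
    return reg.dose * KA / V * sum;
  }
  double a_ke = accum(ke, s, m, reg.tau);
  double a_ka = accum(KA, s, m, reg.tau);
  return reg.dose * KA / (V * (KA - ke)) *
         ((m - a_ke) / ke - (m - a_ka) / KA);
}

// ---- two-compartment, first-order absorption ----

struct TwoCmtCoef {
  double lam[3];  // alpha, beta, KA
  double A[3];    // macro coefficients (C = D*KA/V * sum A_i exp(-lam_i t))
  double scale;   // D*KA/V placeholder filled at call time
};

inline TwoCmtCoef twocmt_coef(double KA, double V, double CL,
                              double K12, double K21) {
  double ke = CL / V;
  double sum = ke + K12 + K21;
  double prod = ke * K21;
  double disc = std::sqrt(std::max(sum * sum - 4.0 * prod, 0.0));
  double alpha = 0.5 * (sum + disc);
  double beta = 0.5 * (sum - disc);
  if (std::fabs(alpha - beta) < 1e-10 * alpha) beta = alpha * (1.0 - 1e-8);
  // keep KA away from the disposition roots (removable singularities)
  if (std::fabs(KA - alpha) < 1e-8 * alpha) KA = alpha * (1.0 + 1e-7);
  if (std::fabs(KA - beta) < 1e-8 * std::fabs(beta)) KA = beta * (1.0 + 1e-7);
  TwoCmtCoef co;
  co.lam[0] = alpha; co.lam[1] = beta; co.lam[2] = KA;
  co.A[0] = (K21 - alpha) / ((KA - alpha) * (beta - alpha));
  co.A[1] = (K21 - beta) / ((KA - beta) * (alpha - beta));
  co.A[2] = (K21 - KA) / ((alpha - KA) * (beta - KA));
  co.scale = KA;
  return co;
}

inline double conc_twocmt(double t, const Regimen& reg,
                          double KA, double V, double CL,
                          double K12, double K21) {
  int m = doses_given(reg, t);
  if (m == 0 || reg.dose <= 0.0) return 0.0;
  TwoCmtCoef co = twocmt_coef(KA, V, CL, K12, K21);
  double s = t - reg.start - (m - 1) * reg.tau;
  double c = 0.0;
  for (int i = 0; i < 3; ++i)
    c += co.A[i] * accum(co.lam[i], s, m, reg.tau);
  c *= reg.dose * co.scale / V;
  return c > 0.0 ? c : 0.0;
}

inline double cauc_twocmt(double T, const Regimen& reg,
                          double KA, double V, double CL,
                          double K12, double K21) {
  int m = doses_given(reg, T);
  if (m == 0 || reg.dose <= 0.0) return 0.0;
  TwoCmtCoef co = twocmt_coef(KA, V, CL, K12, K21);
  double s = T - reg.start - (m - 1) * reg.tau;
  double acc = 0.0;
  for (int i = 0; i < 3; ++i)
    acc += co.A[i] * (m - accum(co.lam[i], s, m, reg.tau)) / co.lam[i];
  return reg.dose * co.scale / V * acc;
}

// ---- one-compartment with Michaelis-Menten elimination ----
// Depot is linear and solved analytically; the central amount (plus
// cumulative AUC and cumulative eliminated amount) is integrated with an
// adaptive Dormand-Prince RK45.

struct MMState { double A, auc, elim; };

inline double mm_depot(double t, const Regimen& reg, double KA) {
  int m = doses_given(reg, t);
  if (m == 0 || reg.dose <= 0.0) return 0.0;
  double s = t - reg.start - (m - 1) * reg.tau;
  return reg.dose * accum(KA, s, m, reg.tau);
}

// depot amount with the number of administered doses frozen at m: inside
// an integration segment the dose count must not flip when a stage lands
// exactly on the next dose time
inline double mm_depot_m(double t, const Regimen& reg, double KA, int m) {
  if (m <= 0 || reg.dose <= 0.0) return 0.0;
  double s = t - reg.start - (m - 1) * reg.tau;
  return reg.dose * accum(KA, s, m, reg.tau);
}

inline void mm_rhs(double t, const MMState& y, MMState& dy,
                   const Regimen& reg, double KA, double V,
                   double VMAX, double KM, int m) {
  double C = y.A / V;
  if (C < 0.0) C = 0.0;
  double elim = VMAX * C / (KM + C);
  dy.A = KA * mm_depot_m(t, reg, KA, m) - elim;
  dy.auc = C;
  dy.elim = elim;
}

// one Dormand-Prince 5(4) step of size h from t; fills y5 with the
// 5th-order solution and returns the scaled embedded error estimate
inline double dopri5_step(double t, double h, const MMState& y, MMState& y5,
                          const Regimen& reg, double KA, double V,
                          double VMAX, double KM, double rtol, double atol,
                          int m) {
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                      e3 = 500.0 / 1113 - 7571.0 / 16695,
                      e4 = 125.0 / 192 - 393.0 / 640,
                      e5 = -2187.0 / 6784 + 92097.0 / 339200,
                      e6 = 11.0 / 84 - 187.0 / 2100,
                      e7 = -1.0 / 40;

  MMState k1, k2, k3, k4, k5, k6, k7, ytmp;
  mm_rhs(t, y, k1, reg, KA, V, VMAX, KM, m);
    ytmp.A = y.A + h * a21 * k1.A;
    ytmp.auc = y.auc + h * a21 * k1.auc;
    ytmp.elim = y.elim + h * a21 * k1.elim;
    mm_rhs(t + c2 * h, ytmp, k2, reg, KA, V, VMAX, KM, m);
    ytmp.A = y.A + h * (a31 * k1.A + a32 * k2.A);
    ytmp.auc = y.auc + h * (a31 * k1.auc + a32 * k2.auc);
    ytmp.elim = y.elim + h * (a31 * k1.elim + a32 * k2.elim);
    mm_rhs(t + c3 * h, ytmp, k3, reg, KA, V, VMAX, KM, m);
    ytmp.A = y.A + h * (a41 * k1.A + a42 * k2.A + a43 * k3.A);
    ytmp.auc = y.auc + h * (a41 * k1.auc + a42 * k2.auc + a43 * k3.auc);
    ytmp.elim = y.elim + h * (a41 * k1.elim + a42 * k2.elim + a43 * k3.elim);
    mm_rhs(t + c4 * h, ytmp, k4, reg, KA, V, VMAX, KM, m);
    ytmp.A = y.A + h * (a51 * k1.A + a52 * k2.A + a53 * k3.A + a54 * k4.A);
    ytmp.auc = y.auc + h * (a51 * k1.auc + a52 * k2.auc + a53 * k3.auc + a54 * k4.auc);
    ytmp.elim = y.elim + h * (a51 * k1.elim + a52 * k2.elim + a53 * k3.elim + a54 * k4.elim);
    mm_rhs(t + c5 * h, ytmp, k5, reg, KA, V, VMAX, KM, m);
    ytmp.A = y.A + h * (a61 * k1.A + a62 * k2.A + a63 * k3.A + a64 * k4.A + a65 * k5.A);
    ytmp.auc = y.auc + h * (a61 * k1.auc + a62 * k2.auc + a63 * k3.auc + a64 * k4.auc + a65 * k5.auc);
    ytmp.elim = y.elim + h * (a61 * k1.elim + a62 * k2.elim + a63 * k3.elim + a64 * k4.elim + a65 * k5.elim);
    mm_rhs(t + h, ytmp, k6, reg, KA, V, VMAX, KM, m);
    y5.A = y.A + h * (b1 * k1.A + b3 * k3.A + b4 * k4.A + b5 * k5.A + b6 * k6.A);
    y5.auc = y.auc + h * (b1 * k1.auc + b3 * k3.auc + b4 * k4.auc + b5 * k5.auc + b6 * k6.auc);
    y5.elim = y.elim + h * (b1 * k1.elim + b3 * k3.elim + b4 * k4.elim + b5 * k5.elim + b6 * k6.elim);
    mm_rhs(t + h, y5, k7, reg, KA, V, VMAX, KM, m);
    double errA = h * (e1 * k1.A + e3 * k3.A + e4 * k4.A + e5 * k5.A + e6 * k6.A + e7 * k7.A);
    double errU = h * (e1 * k1.auc + e3 * k3.auc + e4 * k4.auc + e5 * k5.auc + e6 * k6.auc + e7 * k7.auc);
    double errE = h * (e1 * k1.elim + e3 * k3.elim + e4 * k4.elim + e5 * k5.elim + e6 * k6.elim + e7 * k7.elim);
    double sc1 = atol + rtol * std::fabs(y5.A);
    double sc2 = atol + rtol * std::fabs(y5.auc);
    double sc3 = atol + rtol * std::fabs(y5.elim);
  return std::sqrt(((errA / sc1) * (errA / sc1) +
                    (errU / sc2) * (errU / sc2) +
                    (errE / sc3) * (errE / sc3)) / 3.0);
}

// adaptive integration from t0 to t1 (no dose-time discontinuity inside
// (t0, t1])
inline void mm_step_interval(double t0, double t1, MMState& y,
                             const Regimen& reg, double KA, double V,
                             double VMAX, double KM,
                             double rtol, double atol) {
  if (t1 <= t0) return;
  int m = doses_given(reg, t0 + 1e-9);
  double t = t0;
  double h = std::min(0.5, t1 - t0);
  int n_reject = 0;
  for (int iter = 0; iter < 1000000; ++iter) {
    if (t >= t1 - 1e-12) break;
    if (t + h > t1) h = t1 - t;
    MMState y5;
    double err = dopri5_step(t, h, y, y5, reg, KA, V, VMAX, KM, rtol, atol,
                             m);
    if (err <= 1.0 || h < 1e-10) {
      t += h;
      y = y5;
      n_reject = 0;
      double fac = err > 0.0 ? 0.9 * std::pow(err, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      if (++n_reject > 60) throw std::runtime_error("MM ODE step failure");
      h *= std::max(0.1, 0.9 * std::pow(err, -0.2));
    }
  }
}

// fixed-grid integration from t0 to t1 within one dosing interval: the
// step sequence is log-spaced from the interval's dose time and depends
// only on the time axis, never on the state, so the solution varies
// smoothly with the parameters (clean finite-difference sensitivities for
// estimation; accuracy is fixed by n_sub rather than error-controlled)
inline void mm_step_fixed(double t0, double t1, MMState& y,
                          const Regimen& reg, double KA, double V,
                          double VMAX, double KM, int n_sub) {
  if (t1 <= t0) return;
  int m = doses_given(reg, t0 + 1e-9);
  double a = (m >= 1) ? reg.start + (m - 1) * reg.tau : reg.start;
  const double r = 8.0;
  const double den = std::expm1(r);
  double prev = t0;
  MMState y5;
  for (int i = 1; i <= n_sub; ++i) {
    double tp = a + std::expm1(r * i / n_sub) / den * reg.tau;
    if (tp <= prev + 1e-12) continue;
    if (tp >= t1 - 1e-12) tp = t1;
    dopri5_step(prev, tp - prev, y, y5, reg, KA, V, VMAX, KM, 1.0, 1.0, m);
    y = y5;
    prev = tp;
    if (prev >= t1 - 1e-12) break;
  }
  // past the grid (only after the final dose): continue in tau/8 strides
  while (prev < t1 - 1e-12) {
    double tp = std::min(t1, prev + reg.tau / 8.0);
    dopri5_step(prev, tp - prev, y, y5, reg, KA, V, VMAX, KM, 1.0, 1.0, m);
    y = y5;
    prev = tp;
  }
}

// evaluate concentration (and cumulative AUC / eliminated amount) at sorted
// output times
inline void mm_profile(const std::vector<double>& times, const Regimen& reg,
                       double KA, double V, double VMAX, double KM,
                       double rtol, double atol,
                       std::vector<double>& conc, std::vector<double>& cauc,
                       std::vector<double>& elim, int n_fixed = 0) {
  size_t n = times.size();
  conc.assign(n, 0.0);
  cauc.assign(n, 0.0);
  elim.assign(n, 0.0);
  if (reg.dose <= 0.0 || reg.n_doses <= 0) return;
  MMState y = {0.0, 0.0, 0.0};
  double t = reg.start;
  for (size_t i = 0; i < n; ++i) {
    double target = times[i];
    if (target <= t + 1e-12) {
      double C = y.A / V;
      conc[i] = C > 0.0 ? C : 0.0;
      cauc[i] = y.auc; elim[i] = y.elim;
      continue;
    }
    // step across dose-time breakpoints up to the target
    while (t < target - 1e-12) {
      int m = doses_given(reg, t + 1e-9);
      double next_dose = (m < reg.n_doses)
        ? reg.start + m * reg.tau : std::numeric_limits<double>::infinity();
      double t_stop = std::min(target, next_dose);
      if (n_fixed > 0)
        mm_step_fixed(t, t_stop, y, reg, KA, V, VMAX, KM, n_fixed);
      else
        mm_step_interval(t, t_stop, y, reg, KA, V, VMAX, KM, rtol, atol);
      t = t_stop;
    }
    double C = y.A / V;
    conc[i] = C > 0.0 ? C : 0.0;
    cauc[i] = y.auc; elim[i] = y.elim;
  }
}

// ---- generic prediction over a parameter vector ----

inline void predict_model(int model, const double* p,
                          const std::vector<double>& times,
                          const Regimen& reg, double rtol, double atol,
                          std::vector<double>& out, int n_fixed = 0) {
  size_t n = times.size();
  out.resize(n);
  switch (model) {
  case 0:
    for (size_t i = 0; i < n; ++i) out[i] = p[0];
    break;
  case 1:
    for (size_t i = 0; i < n; ++i)
      out[i] = conc_onecmt(times[i], reg, p[0], p[1], p[2]);
    break;
  case 2: {
    std::vector<double> cc, uu, ee;
    mm_profile(times, reg, p[0], p[1], p[2], p[3], rtol, atol, cc, uu, ee,
               n_fixed);
    out = cc;
    break;
  }
  case 3:
    for (size_t i = 0; i < n; ++i)
      out[i] = conc_twocmt(times[i], reg, p[0], p[1], p[2], p[3], p[4]);
    break;
  default:
    throw std::invalid_argument("unknown model code");
  }
}

}  // namespace tks

#endif
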
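#include <Rcpp.h>
using namespace Rcpp;

// Hill curves; must match the R-level curve functions (the R side verifies
// the returned states against its own curves via the equilibrium residual).
static inline double fl_active(double l) {
  double d = l - 1.0;
  return std::exp(-d * d / 0.45);
}
static inline double fl_active_d(double l) {
  return -2.0 * (l - 1.0) / 0.45 * fl_active(l);
}
static inline double fl_passive(double l) {
  if (l <= 1.0) return 0.0;
  return (std::exp(10.0 * (l - 1.0)) - 1.0) / (std::exp(5.0) - 1.0);
}
static inline double fl_passive_d(double l) {
  if (l <= 1.0) return 0.0;
  return 10.0 * std::exp(10.0 * (l - 1.0)) / (std::exp(5.0) - 1.0);
}
static inline double fvel(double v) {
  if (v < 0.0) {
    double num = 1.0 + v;
    if (num <= 0.0) return 0.0;
    return num / (1.0 - v / 0.25);
  }
  return 1.0 + 0.4 * v / (v + 0.2);
}
static inline double fvel_d(double v) {
  if (v < 0.0) {
    if (1.0 + v <= 0.0) return 0.0;
    double den = 1.0 - 4.0 * v;
    return 5.0 / (den * den);
  }
  double den = v + 0.2;
  return 0.08 / (den * den);
}
static inline double ften(double eps, double Fmax) {
  if (eps <= 0.0) return 0.0;
  if (eps < 0.0127) return 1480.3 * Fmax * eps * eps;
  return (37.5 * eps - 0.2375) * Fmax;
}
static inline double ften_d(double eps, double Fmax) {
  if (eps <= 0.0) return 0.0;
  if (eps < 0.0127) return 2.0 * 1480.3 * Fmax * eps;
  return 37.5 * Fmax;
}

struct Resid {
  double r, slope, lm, cosphi, vt, Fm, Ft, eps;
};

// Equilibrium residual Ft(lt) - Fm cos(phi) at one step, implicit in the
// step's own fiber velocity (backward difference against lm_prev).
static Resid eval_resid(double lt, double lmt, double a, double lm_prev,
                        bool use_prev, double fixed_vt, bool fixed_v,
                        double Fmax, double lm0, double lst, double h,
                        double inv_dtv) {
  Resid out;
  double x = lmt - lt;
  double lm = std::sqrt(x * x + h * h);
  double cosphi = x / lm;
  double ltil = lm / lm0;
  double vt;
  if (fixed_v) vt = fixed_vt;
  else if (use_prev) vt = (lm - lm_prev) * inv_dtv;
  else vt = 0.0;
  double fv = fvel(vt);
  double Fm = Fmax * (fl_active(ltil) * fv * a + fl_passive(ltil));
  double eps = (lt - lst) / lst;
  double Ft = ften(eps, Fmax);
  out.r = Ft - Fm * cosphi;
  // analytic slope d(resid)/d(lt) for Newton (approximate is fine; a
  // sign-bracket bisection safeguards every step)
  double dlm_dlt = -cosphi;
  double dvt_dlt = (fixed_v || !use_prev) ? 0.0 : dlm_dlt * inv_dtv;
  double dFm_dlt = Fmax * ((fl_active_d(ltil) * fv * a + fl_passive_d(ltil)) *
                             dlm_dlt / lm0 +
                           fl_active(ltil) * a * fvel_d(vt) * dvt_dlt);
  double dcos_dlt = -(1.0 - cosphi * cosphi) / lm;
  out.slope = ften_d(eps, Fmax) / lst - (dFm_dlt * cosphi + Fm * dcos_dlt);
  out.lm = lm; out.cosphi = cosphi; out.vt = vt; out.Fm = Fm; out.Ft = Ft;
  out.eps = eps;
  return out;
}

// [[Rcpp::export(name = ".mtu_solve_cpp")]]
List mtu_solve_cpp(NumericVector a, NumericVector lmt, double Fmax,
                   double lm0, double lst, double phi0, double vmax,
                   double rate, NumericVector vtilde, bool fixed_v,
                   double tol) {
  int n = a.size();
  NumericVector lm(n), lt(n), vt(n), eps(n), Fm(n), Ft(n), cosphi(n);
  double h = lm0 * std::sin(phi0);
  double inv_dtv = rate / (vmax * lm0);
  double lm_prev = 0.0;
  double lt_guess = NA_REAL;
  double resid_max = 0.0;
  for (int k = 0; k < n; ++k) {
    bool use_prev = k > 0;
    double fv_k = fixed_v ? vtilde[k] : 0.0;
    double lo = 1e-7, hi = lmt[k] - 1e-9;
    if (hi <= lo) stop("MTU length too short at step %d", k + 1);
    double x = ISNAN(lt_guess) ? 0.5 * (lo + hi)
                               : std::min(std::max(lt_guess, lo), hi);
    Resid rs = eval_resid(x, lmt[k], a[k], lm_prev, use_prev, fv_k, fixed_v,
                          Fmax, lm0, lst, h, inv_dtv);
    // residual is <= 0 at lo and >= 0 at hi (slack tendon carries no
    // force; a near-zero-length fiber projects none)
    for (int it = 0; it < 200 && std::fabs(rs.r) > tol; ++it) {
      if (rs.r > 0.0) hi = x; else lo = x;
      double step_newton = (rs.slope > 1e-12) ? rs.r / rs.slope : 0.0;
      double xn = x - step_newton;
      if (step_newton == 0.0 || xn <= lo || xn >= hi) xn = 0.5 * (lo + hi);
      if (xn == x) break;
      x = xn;
      rs = eval_resid(x, lmt[k], a[k], lm_prev, use_prev, fv_k, fixed_v,
                      Fmax, lm0, lst, h, inv_dtv);
    }
    if (std::fabs(rs.r) > resid_max) resid_max = std::fabs(rs.r);
    lt[k] = x; lm[k] = rs.lm; vt[k] = rs.vt; eps[k] = rs.eps;
    Fm[k] = rs.Fm; Ft[k] = rs.Ft; cosphi[k] = rs.cosphi;
    lm_prev = rs.lm;
    lt_guess = x;
  }
  return List::create(_["lm"] = lm, _["lt"] = lt, _["vtil"] = vt,
                      _["eps"] = eps, _["Fm"] = Fm, _["Ft"] = Ft,
                      _["cosphi"] = cosphi, _["resid_max"] = resid_max);
}
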
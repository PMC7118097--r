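// Core numerical kernels for the wrist neuro-musculoskeletal model:
// rigid-tendon Hill muscle forces, fixed-step RK4 forward dynamics with
// zero-order-hold excitations, and a direct-form-II IIR filter.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

constexpr int NM = 6; // muscles
constexpr int ND = 3; // degrees of freedom (FE, RU, PS)

struct Model {
  double fmax[NM], lopt[NM], vmax[NM], tact[NM], tdeact[NM];
  double R[NM][ND];              // signed moment arms, m
  double I[ND], K[ND], B[ND];    // inertia, passive stiffness, damping
  double qmin[ND], qmax[ND], qrest[ND];
  double fl_width, fp_k, fp_c, fv_av, fv_ecc_gain, fv_ecc_k;
};

Model unpack(const List& m) {
  Model md;
  NumericVector fmax = m["f_max"], lopt = m["l_opt"], vmax = m["v_max"],
                tact = m["tau_act"], tdeact = m["tau_deact"];
  NumericMatrix R = m["moment_arms"];
  NumericVector I = m["inertia"], K = m["stiffness"], B = m["damping"],
                qmin = m["q_min"], qmax = m["q_max"], qrest = m["q_rest"];
  List sh = m["shape"];
  for (int j = 0; j < NM; ++j) {
    md.fmax[j] = fmax[j]; md.lopt[j] = lopt[j]; md.vmax[j] = vmax[j];
    md.tact[j] = tact[j]; md.tdeact[j] = tdeact[j];
    for (int d = 0; d < ND; ++d) md.R[j][d] = R(j, d);
  }
  for (int d = 0; d < ND; ++d) {
    md.I[d] = I[d]; md.K[d] = K[d]; md.B[d] = B[d];
    md.qmin[d] = qmin[d]; md.qmax[d] = qmax[d]; md.qrest[d] = qrest[d];
  }
  md.fl_width = sh["fl_width"]; md.fp_k = sh["fp_k"]; md.fp_c = sh["fp_c"];
  md.fv_av = sh["fv_av"]; md.fv_ecc_gain = sh["fv_ecc_gain"];
  md.fv_ecc_k = sh["fv_ecc_k"];
  return md;
}

inline double flen(const Model& md, double lt) {
  double z = (lt - 1.0) / md.fl_width;
  return std::exp(-z * z);
}

inline double fpas(const Model& md, double lt) {
  return lt > 1.0 ? md.fp_c * (std::exp(md.fp_k * (lt - 1.0)) - 1.0) : 0.0;
}

// u = normalized fiber velocity (lengthening positive), fv(0) = 1
inline double fvel(const Model& md, double u) {
  if (u < 0.0) {
    if (u <= -1.0) return 0.0;
    return (1.0 + u) / (1.0 - u / md.fv_av);
  }
  return 1.0 + md.fv_ecc_gain * u / (u + md.fv_ecc_k);
}

// fiber length/velocity from joint state (rigid tendon, constant moment arms)
inline void fiber(const Model& md, int j, const double* q, const double* qdot,
                  double& lt, double& vnorm) {
  double l = md.lopt[j], ldot = 0.0;
  for (int d = 0; d < ND; ++d) {
    l -= md.R[j][d] * (q[d] - md.qrest[d]);
    ldot -= md.R[j][d] * qdot[d];
  }
  lt = l / md.lopt[j];
  vnorm = ldot / (md.lopt[j] * md.vmax[j]);
}

inline double force_one(const Model& md, int j, double a, const double* q,
                        const double* qdot) {
  double lt, vn;
  fiber(md, j, q, qdot, lt, vn);
  if (lt <= 0.0) stop("normalized fiber length <= 0 (model out of range)");
  double F = md.fmax[j] * (a * flen(md, lt) * fvel(md, vn) + fpas(md, lt));
  return F > 0.0 ? F : 0.0;
}

// qddot from joint state + activations; mask zeroes muscle torque per DoF
inline void accel(const Model& md, const double* q, const double* qdot,
                  const double* a, const int* mask, double* qdd) {
  double F[NM];
  for (int j = 0; j < NM; ++j) F[j] = force_one(md, j, a[j], q, qdot);
  for (int d = 0; d < ND; ++d) {
    double tau = 0.0;
    for (int j = 0; j < NM; ++j) tau += md.R[j][d] * F[j];
    if (mask && mask[d] == 0) tau = 0.0;
    tau -= md.K[d] * (q[d] - md.qrest[d]) + md.B[d] * qdot[d];
    qdd[d] = tau / md.I[d];
  }
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_muscle_forces")]]
NumericVector cpp_muscle_forces(List model, NumericVector a, NumericVector q,
                                NumericVector qdot) {
  Model md = unpack(model);
  NumericVector out(NM);
  for (int j = 0; j < NM; ++j)
    out[j] = force_one(md, j, a[j], REAL(q), REAL(qdot));
  return out;
}

// Active-force gain (f_max * f_l * f_v) and passive force per muscle at the
// given joint state: the static-optimization problem is linear in a with
// these coefficients.
//' @noRd
// [[Rcpp::export(name = ".cpp_force_components")]]
List cpp_force_components(List model, NumericVector q, NumericVector qdot) {
  Model md = unpack(model);
  NumericVector gain(NM), passive(NM), ltilde(NM);
  for (int j = 0; j < NM; ++j) {
    double lt, vn;
    fiber(md, j, REAL(q), REAL(qdot), lt, vn);
    if (lt <= 0.0) stop("normalized fiber length <= 0 (model out of range)");
    gain[j] = md.fmax[j] * flen(md, lt) * fvel(md, vn);
    passive[j] = md.fmax[j] * fpas(md, lt);
    ltilde[j] = lt;
  }
  return List::create(_["gain"] = gain, _["passive"] = passive,
                      _["ltilde"] = ltilde);
}

// Forward dynamics: RK4 on (q, qdot) at fixed dt; activations follow the
// exact exponential solution of da/dt = (u - a)/tau within each substep
// (u is zero-order-held on the control grid of step h). Joint limits are
// enforced by clamp-and-zero-velocity. dof_mask (n_ctrl x 3, 0/1) zeroes the
// muscle torque on suppressed DoFs; pass R_NilValue for no gating.
//' @noRd
// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(List model, NumericMatrix U, double h, double t_end,
                  double dt, NumericVector q0, NumericVector qdot0,
                  NumericVector a0, Nullable<IntegerMatrix> dof_mask) {
  Model md = unpack(model);
  const int nctrl = U.nrow();
  const int nstep = (int)std::lround(t_end / dt);
  IntegerMatrix M;
  bool has_mask = dof_mask.isNotNull();
  if (has_mask) {
    M = IntegerMatrix(dof_mask);
    if (M.nrow() != nctrl) stop("dof_mask rows must match excitation rows");
  }

  NumericVector time(nstep + 1);
  NumericMatrix Q(nstep + 1, ND), QD(nstep + 1, ND), A(nstep + 1, NM);
  double q[ND], qd[ND], a[NM];
  for (int d = 0; d < ND; ++d) { q[d] = q0[d]; qd[d] = qdot0[d]; }
  for (int j = 0; j < NM; ++j) a[j] = a0[j];

  auto record = [&](int i, double t) {
    time[i] = t;
    for (int d = 0; d < ND; ++d) { Q(i, d) = q[d]; QD(i, d) = qd[d]; }
    for (int j = 0; j < NM; ++j) A(i, j) = a[j];
  };
  record(0, 0.0);

  double u[NM], tau_a[NM], amid[NM], aend[NM];
  int maskbuf[ND];
  for (int i = 0; i < nstep; ++i) {
    double t = i * dt;
    int k = (int)std::floor((t + 1e-12) / h);
    if (k >= nctrl) k = nctrl - 1;
    const int* mask = nullptr;
    if (has_mask) {
      for (int d = 0; d < ND; ++d) maskbuf[d] = M(k, d);
      mask = maskbuf;
    }
    for (int j = 0; j < NM; ++j) {
      u[j] = U(k, j);
      tau_a[j] = (u[j] > a[j]) ? md.tact[j] : md.tdeact[j];
      double e1 = std::exp(-0.5 * dt / tau_a[j]);
      amid[j] = u[j] + (a[j] - u[j]) * e1;
      aend[j] = u[j] + (a[j] - u[j]) * e1 * e1;
    }
    // RK4 stages for (q, qdot); activation evaluated at stage times
    double k1q[ND], k1v[ND], k2q[ND], k2v[ND], k3q[ND], k3v[ND],
        k4q[ND], k4v[ND], qt[ND], vt[ND], qdd[ND];
    accel(md, q, qd, a, mask, qdd);
    for (int d = 0; d < ND; ++d) { k1q[d] = qd[d]; k1v[d] = qdd[d]; }
    for (int d = 0; d < ND; ++d) {
      qt[d] = q[d] + 0.5 * dt * k1q[d]; vt[d] = qd[d] + 0.5 * dt * k1v[d];
    }
    accel(md, qt, vt, amid, mask, qdd);
    for (int d = 0; d < ND; ++d) { k2q[d] = vt[d]; k2v[d] = qdd[d]; }
    for (int d = 0; d < ND; ++d) {
      qt[d] = q[d] + 0.5 * dt * k2q[d]; vt[d] = qd[d] + 0.5 * dt * k2v[d];
    }
    accel(md, qt, vt, amid, mask, qdd);
    for (int d = 0; d < ND; ++d) { k3q[d] = vt[d]; k3v[d] = qdd[d]; }
    for (int d = 0; d < ND; ++d) {
      qt[d] = q[d] + dt * k3q[d]; vt[d] = qd[d] + dt * k3v[d];
    }
    accel(md, qt, vt, aend, mask, qdd);
    for (int d = 0; d < ND; ++d) { k4q[d] = vt[d]; k4v[d] = qdd[d]; }
    for (int d = 0; d < ND; ++d) {
      q[d] += dt / 6.0 * (k1q[d] + 2 * k2q[d] + 2 * k3q[d] + k4q[d]);
      qd[d] += dt / 6.0 * (k1v[d] + 2 * k2v[d] + 2 * k3v[d] + k4v[d]);
      if (q[d] < md.qmin[d]) { q[d] = md.qmin[d]; if (qd[d] < 0) qd[d] = 0; }
      if (q[d] > md.qmax[d]) { q[d] = md.qmax[d]; if (qd[d] > 0) qd[d] = 0; }
      if (!std::isfinite(q[d]) || !std::isfinite(qd[d]))
        stop("integration failure: non-finite state");
    }
    for (int j = 0; j < NM; ++j) a[j] = aend[j];
    record(i + 1, (i + 1) * dt);
  }
  return List::create(_["time"] = time, _["q"] = Q, _["qdot"] = QD,
                      _["a"] = A);
}

// Direct-form II transposed IIR filter; optional initial state (e.g. the
// steady-state conditions used by zero-phase filtering).
//' @noRd
// [[Rcpp::export(name = ".cpp_iir")]]
NumericVector cpp_iir(NumericVector b, NumericVector a, NumericVector x,
                      Nullable<NumericVector> zi = R_NilValue) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nw = std::max(na, nb);
  std::vector<double> bb(nw, 0.0), aa(nw, 0.0), w(nw, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  if (zi.isNotNull()) {
    NumericVector z(zi);
    for (int i = 0; i < std::min((int)z.size(), nw); ++i) w[i] = z[i];
  }
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double yi = bb[0] * x[i] + w[0];
    for (int k = 0; k < nw - 1; ++k)
      w[k] = bb[k + 1] * x[i] - aa[k + 1] * yi + w[k + 1];
    y[i] = yi;
  }
  return y;
}
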
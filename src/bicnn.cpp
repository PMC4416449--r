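// Compiled closed-loop trial driver.
//
// Mirrors the pure-R reference path (run_step/step_hemisphere/plant_step)
// operation for operation, including summation order, so the two engines
// agree to floating-point round-off. The compiled path exists because one
// control step touches ~1e5 synapses and a trial runs 1e4-1e5 steps.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Proj {
  int nt = 0, f = 0;
  const int* idx = nullptr;     // target-major, 0-based source indices
  const double* w = nullptr;    // same layout as idx
};

Proj get_proj(const List& pack, const char* name) {
  List p = pack[name];
  Proj pr;
  pr.nt = as<int>(p["nt"]);
  pr.f = as<int>(p["f"]);
  pr.idx = INTEGER(as<IntegerVector>(p["idx"]));
  pr.w = REAL(as<NumericVector>(p["w"]));
  return pr;
}

// sum over one target's afferents of (w * y_src), optionally elementwise
// scaled; same accumulation order as R's rowSums over ascending columns.
inline double drive(const Proj& p, int t, const double* y) {
  const int* ix = p.idx + (size_t)t * p.f;
  const double* w = p.w + (size_t)t * p.f;
  double s = 0.0;
  for (int j = 0; j < p.f; ++j) s += w[j] * y[ix[j]];
  return s;
}

inline double drive_scaled(const Proj& p, int t, const double* y,
                           double scale) {
  const int* ix = p.idx + (size_t)t * p.f;
  const double* w = p.w + (size_t)t * p.f;
  double s = 0.0;
  for (int j = 0; j < p.f; ++j) s += (w[j] * y[ix[j]]) * scale;
  return s;
}

inline double sig01(double x, double sigma, double mu) {
  return 1.0 / (1.0 + std::exp(-sigma * (x - mu)));
}

// Compressed-sparse-row projection: per-target variable afferent counts.
// Used for GC-originating projections after knocked-down sources (whose
// rates are exactly 0, contributing exactly 0.0 to every sum) are dropped.
struct ProjCSR {
  int nt = 0;
  const int* ptr = nullptr;      // length nt + 1
  const int* idx = nullptr;
  const double* w = nullptr;
};

ProjCSR get_csr(const List& pack, const char* name) {
  List p = pack[name];
  ProjCSR pr;
  pr.nt = as<int>(p["nt"]);
  pr.ptr = INTEGER(as<IntegerVector>(p["ptr"]));
  pr.idx = INTEGER(as<IntegerVector>(p["idx"]));
  pr.w = REAL(as<NumericVector>(p["w"]));
  return pr;
}

inline double drive_csr(const ProjCSR& p, int t, const double* y,
                        double scale) {
  double s = 0.0;
  for (int j = p.ptr[t]; j < p.ptr[t + 1]; ++j)
    s += (p.w[j] * y[p.idx[j]]) * scale;
  return s;
}

struct Hemi {
  int n_mf, n_go, n_gc, n_bc;
  double comp, sigma, mu;
  Proj mf_go, bc_go, mf_gc, go_gc, pc_bc, bc_pc;
  ProjCSR pf_go, pf_bc;          // active-source edges only
  Proj pf_pc;                    // full layout (plastic weights)
  const int* act_idx = nullptr;  // 0-based active GC indices
  int n_act = 0;
  const int* act_pos = nullptr;  // positions j in pf_pc with active source
  std::vector<double> w_pf;      // working copy of PF->PC weights
  std::vector<double> y_gc[2], y_go[2], y_bc[2];
  double y_pc[2] = {0.0, 0.0};
  double x_pc = 0.0;
  int cur = 0;                   // buffer in use for "current"

  void init(const List& pack) {
    IntegerVector n = pack["counts"];
    n_mf = n[0]; n_go = n[1]; n_gc = n[2]; n_bc = n[3];
    comp = as<double>(pack["comp"]);
    sigma = as<double>(pack["sigma"]);
    mu = as<double>(pack["mu"]);
    mf_go = get_proj(pack, "mf_go"); bc_go = get_proj(pack, "bc_go");
    mf_gc = get_proj(pack, "mf_gc"); go_gc = get_proj(pack, "go_gc");
    pc_bc = get_proj(pack, "pc_bc"); bc_pc = get_proj(pack, "bc_pc");
    pf_go = get_csr(pack, "pf_go_csr");
    pf_bc = get_csr(pack, "pf_bc_csr");
    pf_pc = get_proj(pack, "pf_pc");
    IntegerVector ai = pack["act_idx"];
    act_idx = INTEGER(ai); n_act = ai.size();
    act_pos = INTEGER(as<IntegerVector>(pack["act_pos"]));
    NumericVector w0 = as<List>(pack["pf_pc"])["w"];
    w_pf.assign(w0.begin(), w0.end());
    pf_pc.w = w_pf.data();
    for (int b = 0; b < 2; ++b) {
      y_gc[b].assign(n_gc, 0.0);
      y_go[b].assign(n_go, 0.0);
      y_bc[b].assign(n_bc, 0.0);
    }
  }

  void step(const double* y_mf) {
    int prv = cur, nxt = 1 - cur;
    const double* gc_p = y_gc[prv].data();
    const double* go_p = y_go[prv].data();
    const double* bc_p = y_bc[prv].data();
    double* gc_c = y_gc[nxt].data();
    double* go_c = y_go[nxt].data();
    double* bc_c = y_bc[nxt].data();
    // GO <- MF(cur) + PF(prev, compensated) - BC(prev)
    for (int g = 0; g < n_go; ++g) {
      double x = drive(mf_go, g, y_mf) + drive_csr(pf_go, g, gc_p, comp)
        - drive(bc_go, g, bc_p);
      go_c[g] = sig01(x, sigma, mu);
    }
    // GC <- MF(cur) - GO(prev); knocked-down GCs stay exactly 0
    for (int a = 0; a < n_act; ++a) {
      int c = act_idx[a];
      double x = drive(mf_gc, c, y_mf) - drive(go_gc, c, go_p);
      gc_c[c] = sig01(x, sigma, mu);
    }
    // BC <- PF(cur, compensated) - PC(prev, as nonnegative rate in [0,1])
    double ypc_prev[1] = {y_pc[prv] + 0.5};
    for (int b = 0; b < n_bc; ++b) {
      double x = drive_csr(pf_bc, b, gc_c, comp)
        - drive(pc_bc, b, ypc_prev);
      bc_c[b] = sig01(x, sigma, mu);
    }
    // PC <- PF(cur, compensated) - BC(cur); single PC per hemisphere
    double pf_drive = 0.0;
    for (int a = 0; a < n_act; ++a) {
      int j = act_pos[a];
      pf_drive += (w_pf[j] * gc_c[pf_pc.idx[j]]) * comp;
    }
    x_pc = pf_drive - drive(bc_pc, 0, bc_c);
    y_pc[nxt] = sig01(x_pc, sigma, mu) - 0.5;
    cur = nxt;
  }

  void plasticity(double cf, double gltd, double gltp, double spont) {
    const int* ix = pf_pc.idx;
    const double* y = y_gc[cur].data();
    double* w = w_pf.data();
    if (cf > spont) {
      for (int a = 0; a < n_act; ++a) {
        int j = act_pos[a];
        double nw = w[j] + (-gltd * cf * y[ix[j]]);
        w[j] = nw > 0.0 ? nw : 0.0;
      }
    } else {
      for (int a = 0; a < n_act; ++a) {
        int j = act_pos[a];
        double nw = w[j] + gltp * y[ix[j]];
        w[j] = nw > 0.0 ? nw : 0.0;
      }
    }
  }
};

// ---- plants ---------------------------------------------------------------

void plant_deriv(int kind, const double* p, const double* s, double u,
                 double* ds) {
  if (kind == 1) {                       // DC motor: phi, omega, i
    ds[0] = s[1];
    ds[1] = (p[2] * s[2] - p[1] * s[1]) / p[0];          // (kt i - b w)/J
    ds[2] = (u - p[4] * s[2] - p[3] * s[1]) / p[5];      // (u - R i - ke w)/L
  } else if (kind == 2) {                // robot: phi, dphi, th, dth
    double m_b = p[0], m_w = p[1], l = p[2], r = p[3], I_b = p[4],
      I_w = p[5], b_f = p[6], km = p[7], g = p[8];
    double th = s[2], dth = s[3], dphi = s[1];
    double tau = km * u;
    double m11 = (m_w + m_b) * r * r + I_w;
    double m12 = m_b * r * l * std::cos(th);
    double m22 = m_b * l * l + I_b;
    double fr = b_f * (dphi - dth);
    double r1 = tau - fr + m_b * r * l * dth * dth * std::sin(th);
    double r2 = -tau + fr + m_b * g * l * std::sin(th);
    double det = m11 * m22 - m12 * m12;
    ds[0] = dphi;
    ds[1] = (m22 * r1 - m12 * r2) / det;
    ds[2] = dth;
    ds[3] = (m11 * r2 - m12 * r1) / det;
  } else {                               // quad: x, vx, th, dth
    double m = p[0], I = p[1], c_x = p[2], c_th = p[3], g = p[5];
    double th = s[2];
    double thc = th > 1.2 ? 1.2 : (th < -1.2 ? -1.2 : th);
    ds[0] = s[1];
    ds[1] = g * std::tan(thc) - c_x / m * s[1];
    ds[2] = s[3];
    ds[3] = (u - c_th * s[3]) / I;
  }
}

bool plant_rk4(int kind, const double* p, double* s, int ns, double u,
               double dt, int n_sub, double fall_threshold) {
  double h = dt / n_sub;
  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  for (int k = 0; k < n_sub; ++k) {
    plant_deriv(kind, p, s, u, k1);
    for (int i = 0; i < ns; ++i) tmp[i] = s[i] + h / 2 * k1[i];
    plant_deriv(kind, p, tmp, u, k2);
    for (int i = 0; i < ns; ++i) tmp[i] = s[i] + h / 2 * k2[i];
    plant_deriv(kind, p, tmp, u, k3);
    for (int i = 0; i < ns; ++i) tmp[i] = s[i] + h * k3[i];
    plant_deriv(kind, p, tmp, u, k4);
    for (int i = 0; i < ns; ++i)
      s[i] = s[i] + h / 6 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
  }
  bool ok = true;
  for (int i = 0; i < ns; ++i) if (!std::isfinite(s[i])) ok = false;
  if (ok && kind == 2 && std::fabs(s[2]) > fall_threshold) ok = false;
  return ok;
}

inline double ref_pos(const double* amp, const double* freq,
                      const double* ph, int n, double t) {
  double pos = 0.0;
  for (int k = 0; k < n; ++k)
    pos += amp[k] * std::sin(2.0 * M_PI * freq[k] * t + ph[k]);
  return pos;
}

inline double ref_vel(const double* amp, const double* freq,
                      const double* ph, int n, double t) {
  double vel = 0.0;
  for (int k = 0; k < n; ++k)
    vel += amp[k] * (2.0 * M_PI * freq[k]) *
      std::cos(2.0 * M_PI * freq[k] * t + ph[k]);
  return vel;
}

inline double clip(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

} // namespace

// [[Rcpp::export]]
List cpp_run_trial(List packL, List packR, int plant_id,
                   NumericVector plant_par, NumericVector state0,
                   double u_max, double fall_threshold,
                   NumericVector pd, List mfspec, List cfspec, List ctrl,
                   List traj1, List traj2) {
  const double dt = as<double>(ctrl["dt"]);
  const int n_sub = as<int>(ctrl["n_sub"]);
  const double g_cb = as<double>(ctrl["g_cb"]);
  const int n_steps = as<int>(ctrl["n_steps"]);
  const int n_cycles = as<int>(ctrl["n_cycles"]);
  IntegerVector cycle_of = ctrl["cycle_of"];      // 1-based, length n_steps
  const int switch_step = as<int>(ctrl["switch_step"]);  // 0 = no switch
  const bool rec_tr = as<bool>(ctrl["record_traces"]);
  const bool rec_w = as<bool>(ctrl["record_weights"]);
  const bool pd_only = as<bool>(ctrl["pd_only"]);
  const bool plast_on = as<bool>(ctrl["plast_on"]);

  NumericVector t1a = traj1["amp"], t1f = traj1["freq"], t1p = traj1["phase"];
  bool has2 = traj2.size() > 0;
  NumericVector t2a, t2f, t2p;
  if (has2) { t2a = traj2["amp"]; t2f = traj2["freq"]; t2p = traj2["phase"]; }

  IntegerVector mf_sig = mfspec["sig"];           // 0-based per fiber
  NumericVector mf_pol = mfspec["pol"];
  NumericVector mf_gain = mfspec["gain"];         // per signal
  const int n_mf = mf_sig.size();

  const double g_pref = as<double>(cfspec["g_pref"]);
  const double g_np = as<double>(cfspec["g_np"]);
  const double gltd = as<double>(cfspec["gamma_ltd"]);
  const double gltp = as<double>(cfspec["gamma_ltp"]);
  const double spont = as<double>(cfspec["cf_spont"]);

  Hemi L, R;
  if (!pd_only) { L.init(packL); R.init(packR); }

  double s[4];
  int ns = state0.size();
  for (int i = 0; i < ns; ++i) s[i] = state0[i];
  const double* pp = REAL(plant_par);

  std::vector<double> y_mf(n_mf, 0.0), sigv(8, 0.0);
  std::vector<double> sq(n_cycles, 0.0);
  std::vector<int> cnt(n_cycles, 0);
  NumericMatrix trace = rec_tr ? NumericMatrix(n_steps, 10)
                               : NumericMatrix(0, 0);
  int n_gc = pd_only ? 0 : L.n_gc;
  NumericMatrix snapL = rec_w ? NumericMatrix(n_cycles, n_gc)
                              : NumericMatrix(0, 0);
  NumericMatrix snapR = rec_w ? NumericMatrix(n_cycles, n_gc)
                              : NumericMatrix(0, 0);

  bool fallen = false;
  int fall_step = NA_INTEGER;
  double u_prev = 0.0;
  double sw_offset = switch_step * dt;
  int done_steps = 0;

  for (int k = 0; k < n_steps; ++k) {
    double t = k * dt;
    bool ph2 = has2 && k >= switch_step;
    double tt = ph2 ? (t - sw_offset) : t;
    const double* A = ph2 ? REAL(t2a) : REAL(t1a);
    const double* F = ph2 ? REAL(t2f) : REAL(t1f);
    const double* P = ph2 ? REAL(t2p) : REAL(t1p);
    int nterm = ph2 ? t2a.size() : t1a.size();
    double rpos = ref_pos(A, F, P, nterm, tt);
    double rvel = ref_vel(A, F, P, nterm, tt);

    // sensors -> signals, controlled variable, CF error, PD command
    double controlled, cf_err, u_pd;
    int n_sig;
    if (plant_id == 1) {                 // DC motor
      controlled = s[0];
      sigv[0] = rpos; sigv[1] = rvel;
      sigv[2] = rpos - s[0]; sigv[3] = rvel - s[1]; sigv[4] = u_prev;
      n_sig = 5;
      cf_err = rpos - s[0];
      u_pd = pd[0] * (rpos - s[0]) + pd[1] * (rvel - s[1]);
    } else if (plant_id == 2) {          // robot
      controlled = s[0];
      sigv[0] = rpos; sigv[1] = rvel; sigv[2] = -s[2]; sigv[3] = -s[3];
      sigv[4] = rpos - s[0]; sigv[5] = rvel - s[1]; sigv[6] = u_prev;
      n_sig = 7;
      cf_err = rpos - s[0];
      u_pd = pd[0] * (0 - s[2]) + pd[1] * (0 - s[3]) +
        pd[2] * (rpos - s[0]) + pd[3] * (rvel - s[1]);
    } else {                             // quad
      controlled = s[0];
      double th_max = pp[4];
      double th_ref = clip(pd[0] * (rpos - s[0]) + pd[1] * (rvel - s[1]),
                           -th_max, th_max);
      sigv[0] = rpos; sigv[1] = th_ref; sigv[2] = rpos - s[0];
      sigv[3] = th_ref - s[2]; sigv[4] = rvel - s[1]; sigv[5] = -s[3];
      sigv[6] = u_prev;
      n_sig = 7;
      cf_err = rpos - s[0];
      u_pd = pd[2] * (th_ref - s[2]) + pd[3] * (0 - s[3]);
    }
    (void)n_sig;

    double out = 0.0, cf_l = NA_REAL, cf_r = NA_REAL;
    if (!pd_only) {
      for (int i = 0; i < n_mf; ++i) {
        double r = mf_pol[i] * mf_gain[mf_sig[i]] * sigv[mf_sig[i]];
        y_mf[i] = clip(r, 0.0, 1.0);
      }
      L.step(y_mf.data());
      R.step(y_mf.data());
      double up = cf_err > 0 ? cf_err : 0.0;
      double dn = -cf_err > 0 ? -cf_err : 0.0;
      cf_l = clip(spont + g_pref * up - g_np * dn, 0.0, 1.0);
      cf_r = clip(spont + g_pref * dn - g_np * up, 0.0, 1.0);
      if (plast_on) {
        L.plasticity(cf_l, gltd, gltp, spont);
        R.plasticity(cf_r, gltd, gltp, spont);
      }
      out = clip(R.y_pc[R.cur] - L.y_pc[L.cur], -1.0, 1.0);
    }

    double u = u_pd + g_cb * out;
    double u_sat = clip(u, -u_max, u_max);

    int cyc = cycle_of[k] - 1;
    double e = rpos - controlled;
    sq[cyc] += e * e;
    cnt[cyc] += 1;

    if (rec_tr) {
      trace(k, 0) = t; trace(k, 1) = rpos; trace(k, 2) = controlled;
      trace(k, 3) = u_pd; trace(k, 4) = g_cb * out; trace(k, 5) = u_sat;
      trace(k, 6) = cf_l; trace(k, 7) = cf_r;
      trace(k, 8) = pd_only ? NA_REAL : L.y_pc[L.cur];
      trace(k, 9) = pd_only ? NA_REAL : R.y_pc[R.cur];
    }
    if (rec_w && !pd_only &&
        (k == n_steps - 1 || cycle_of[k + 1] - 1 != cyc)) {
      for (int j = 0; j < L.pf_pc.f; ++j)
        snapL(cyc, L.pf_pc.idx[j]) = L.w_pf[j];
      for (int j = 0; j < R.pf_pc.f; ++j)
        snapR(cyc, R.pf_pc.idx[j]) = R.w_pf[j];
    }

    bool ok = plant_rk4(plant_id, pp, s, ns, u_sat, dt, n_sub,
                        fall_threshold);
    u_prev = u_sat;
    done_steps = k + 1;
    if (!ok) { fallen = true; fall_step = k + 1; break; }
  }

  int done_cycles = fallen ? cycle_of[fall_step - 1] - 1 : n_cycles;
  NumericVector rse(n_cycles, NA_REAL);
  LogicalVector complete(n_cycles);
  for (int c = 0; c < n_cycles; ++c) {
    complete[c] = c < done_cycles;
    if (complete[c] && cnt[c] > 0) rse[c] = std::sqrt(sq[c] / cnt[c]);
  }

  NumericVector state_out(ns);
  for (int i = 0; i < ns; ++i) state_out[i] = s[i];

  List res = List::create(
    _["rse"] = rse, _["complete"] = complete,
    _["fallen"] = fallen, _["fall_step"] = fall_step,
    _["done_steps"] = done_steps, _["state"] = state_out,
    _["trace"] = trace, _["snapL"] = snapL, _["snapR"] = snapR);
  if (!pd_only) {
    res["wL"] = NumericVector(L.w_pf.begin(), L.w_pf.end());
    res["wR"] = NumericVector(R.w_pf.begin(), R.w_pf.end());
  }
  return res;
}
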
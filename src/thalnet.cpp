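// Core numerics: gating-rate kinetics registry and the fixed-step network
// integrator.  Gates and synapses use exact-exponential updates; the membrane
// potential uses an explicit update.  Gate steady states and relaxation
// factors are tabulated on a voltage grid once per run, which is what makes
// whole-network runs at dt = 0.025 ms tractable.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Gating kinetics.  Cortical channel kinetics follow the Traub-type
// single-compartment reduction; thalamic relay (TC) and reticular (RE)
// kinetics follow the Destexhe-type models (T-current, slow T-current,
// anomalous rectifier, shifted Na/K rates).  Q10 corrections are folded into
// the time constants (36 C).
// ---------------------------------------------------------------------------

// x/(exp(x/y)-1) with the removable singularity filled in
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

enum KinId {
  NAF_M = 0, NAF_H, NAP_M, KDR_M, KA_M, KA_H, K2_M, K2_H, KM_M, KC_M,
  CAT_M, CAT_H, CAL_M, AR_M,
  TCNA_M, TCNA_H, TCK_N, RENA_M, RENA_H, REK_N,
  IT_M, IT_H, ITS_M, ITS_H, HTC_M, HTC2_M,
  N_KIN
};

static const double VT_TC = -52.0;  // Na/K threshold shift, thalamic relay
static const double VT_RE = -60.0;  // Na/K threshold shift, thalamic reticular

static void traub_na_m(double v, double vt, double &a, double &b) {
  double u = v - vt;
  a = 0.32 * vtrap(13.0 - u, 4.0);
  b = 0.28 * vtrap(u - 40.0, 5.0);
}
static void traub_na_h(double v, double vt, double &a, double &b) {
  double u = v - vt;
  a = 0.128 * std::exp((17.0 - u) / 18.0);
  b = 4.0 / (1.0 + std::exp((40.0 - u) / 5.0));
}
static void traub_k_n(double v, double vt, double &a, double &b) {
  double u = v - vt;
  a = 0.032 * vtrap(15.0 - u, 5.0);
  b = 0.5 * std::exp((10.0 - u) / 40.0);
}

static void kin_rates(int kid, double v, double &xinf, double &xtau) {
  double a = 0.0, b = 0.0;
  switch (kid) {
  case NAF_M:
    xinf = 1.0 / (1.0 + std::exp((-v - 38.0) / 10.0));
    xtau = (v < -30.0) ? 0.0125 + 0.1525 * std::exp((v + 30.0) / 10.0)
                       : 0.02 + 0.145 * std::exp((-v - 30.0) / 10.0);
    return;
  case NAF_H:
    xinf = 1.0 / (1.0 + std::exp((v + 62.9) / 10.7));
    xtau = 0.225 + 1.125 / (1.0 + std::exp((v + 37.0) / 15.0));
    return;
  case NAP_M:
    xinf = 1.0 / (1.0 + std::exp((-v - 48.0) / 10.0));
    xtau = (v < -40.0) ? 0.025 + 0.14 * std::exp((v + 40.0) / 10.0)
                       : 0.02 + 0.145 * std::exp((-v - 40.0) / 10.0);
    return;
  case KDR_M:
    xinf = 1.0 / (1.0 + std::exp((-v - 29.5) / 10.0));
    xtau = 0.25 + 4.35 * std::exp(-std::fabs(v + 10.0) / 10.0);
    return;
  case KA_M:
    xinf = 1.0 / (1.0 + std::exp((-v - 60.0) / 8.5));
    xtau = 0.185 + 0.5 / (std::exp((v + 35.8) / 19.7) +
                          std::exp((-v - 79.7) / 12.7));
    return;
  case KA_H:
    xinf = 1.0 / (1.0 + std::exp((v + 78.0) / 6.0));
    xtau = (v < -63.0) ? 0.5 / (std::exp((v + 46.0) / 5.0) +
                                std::exp((-v - 238.0) / 37.5))
                       : 9.5;
    return;
  case K2_M:
    xinf = 1.0 / (1.0 + std::exp((-v - 10.0) / 17.0));
    xtau = 4.95 + 0.5 / (std::exp((v - 81.0) / 25.6) +
                         std::exp((-v - 132.0) / 18.0));
    return;
  case K2_H:
    xinf = 1.0 / (1.0 + std::exp((v + 58.0) / 10.6));
    xtau = 60.0 + 0.5 / (std::exp((v - 1.33) / 200.0) +
                         std::exp((-v - 130.0) / 7.1));
    return;
  case KM_M:
    a = 0.02 / (1.0 + std::exp((-v - 20.0) / 5.0));
    b = 0.01 * std::exp((-v - 43.0) / 18.0);
    break;
  case KC_M:
    if (v <= -10.0) {
      a = std::exp((v + 50.0) / 11.0 - (v + 53.5) / 27.0) / 18.975;
      b = 2.0 * std::exp((-v - 53.5) / 27.0) - a;
      if (b < 0.0) b = 0.0;  // rate crossover just below -10 mV
    } else {
      a = 2.0 * std::exp((-v - 53.5) / 27.0);
      b = 0.0;
    }
    break;
  case CAT_M:
    xinf = 1.0 / (1.0 + std::exp((-v - 56.0) / 6.2));
    xtau = 0.204 + 0.333 / (std::exp((v + 15.8) / 18.2) +
                            std::exp((-v - 131.0) / 16.7));
    return;
  case CAT_H:
    xinf = 1.0 / (1.0 + std::exp((v + 80.0) / 4.0));
    xtau = (v < -81.0) ? 0.333 * std::exp((v + 466.0) / 66.6)
                       : 9.32 + 0.333 * std::exp((-v - 21.0) / 10.5);
    return;
  case CAL_M:
    a = 1.6 / (1.0 + std::exp(-0.072 * (v - 5.0)));
    b = 0.02 * vtrap(v + 8.9, 5.0);
    break;
  case AR_M:
    xinf = 1.0 / (1.0 + std::exp((v + 75.0) / 5.5));
    xtau = 1.0 / (std::exp(-14.59 - 0.086 * v) + std::exp(-1.87 + 0.0701 * v));
    return;
  case TCNA_M: traub_na_m(v, VT_TC, a, b); break;
  case TCNA_H: traub_na_h(v, VT_TC, a, b); break;
  case TCK_N:  traub_k_n(v, VT_TC, a, b); break;
  case RENA_M: traub_na_m(v, VT_RE, a, b); break;
  case RENA_H: traub_na_h(v, VT_RE, a, b); break;
  case REK_N:  traub_k_n(v, VT_RE, a, b); break;
  case IT_M: {
    xinf = 1.0 / (1.0 + std::exp(-(v + 59.0) / 6.2));
    double phi = 6.8986;  // 5^((36-24)/10)
    xtau = (0.612 + 1.0 / (std::exp(-(v + 133.8) / 16.7) +
                           std::exp((v + 18.8) / 18.2))) / phi;
    return;
  }
  case IT_H: {
    double phi = 3.7372;  // 3^((36-24)/10)
    xinf = 1.0 / (1.0 + std::exp((v + 83.0) / 4.0));
    xtau = (v < -82.8) ? std::exp((v + 469.8) / 66.6) / phi
                       : (28.0 + std::exp(-(v + 24.8) / 10.5)) / phi;
    return;
  }
  case ITS_M: {
    double phi = 3.0;  // 2.5^((36-24)/10)
    xinf = 1.0 / (1.0 + std::exp(-(v + 52.0) / 7.4));
    xtau = (3.0 + 1.0 / (std::exp((v + 27.0) / 10.0) +
                         std::exp(-(v + 102.0) / 15.0))) / phi;
    return;
  }
  case ITS_H: {
    double phi = 3.0;
    xinf = 1.0 / (1.0 + std::exp((v + 80.0) / 5.0));
    xtau = (85.0 + 1.0 / (std::exp((v + 48.0) / 4.0) +
                          std::exp(-(v + 407.0) / 50.0))) / phi;
    return;
  }
  case HTC_M:
    xinf = 1.0 / (1.0 + std::exp((v + 75.0) / 5.5));
    xtau = 20.0 + 1000.0 / (std::exp((v + 71.5) / 14.2) +
                            std::exp(-(v + 89.0) / 11.6));
    return;
  case HTC2_M:  // hyperpolarized-shifted anomalous rectifier variant
    xinf = 1.0 / (1.0 + std::exp((v + 82.0) / 5.5));
    xtau = 20.0 + 1000.0 / (std::exp((v + 78.5) / 14.2) +
                            std::exp(-(v + 96.0) / 11.6));
    return;
  default:
    stop("unknown kinetics id %d", kid);
  }
  double s = a + b;
  if (s < 1e-9) s = 1e-9;
  xinf = a / s;
  xtau = 1.0 / s;
}

//' @noRd
// [[Rcpp::export(name = "cpp_kin_inf")]]
NumericVector cpp_kin_inf(int kid, NumericVector v) {
  NumericVector out(v.size());
  double xi, xt;
  for (R_xlen_t i = 0; i < v.size(); ++i) {
    kin_rates(kid, v[i], xi, xt);
    out[i] = xi;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = "cpp_kin_tau")]]
NumericVector cpp_kin_tau(int kid, NumericVector v) {
  NumericVector out(v.size());
  double xi, xt;
  for (R_xlen_t i = 0; i < v.size(); ++i) {
    kin_rates(kid, v[i], xi, xt);
    out[i] = xt;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Network integrator
// ---------------------------------------------------------------------------

struct GateTable {
  // tabulated steady state and exponential relaxation factor 1-exp(-dt/tau)
  std::vector<double> inf, efac;
};

static const double V_TAB_MIN = -130.0, V_TAB_MAX = 70.0, V_TAB_DV = 0.05;
static const int V_TAB_N = 4001;

static void build_table(int kid, double dt, GateTable &tab) {
  tab.inf.resize(V_TAB_N);
  tab.efac.resize(V_TAB_N);
  double xi, xt;
  for (int j = 0; j < V_TAB_N; ++j) {
    double v = V_TAB_MIN + j * V_TAB_DV;
    kin_rates(kid, v, xi, xt);
    tab.inf[j] = xi;
    tab.efac[j] = -std::expm1(-dt / xt);
  }
}

static inline double ipow(double x, int n) {
  switch (n) {
  case 0: return 1.0;
  case 1: return x;
  case 2: return x * x;
  case 3: return x * x * x;
  case 4: { double x2 = x * x; return x2 * x2; }
  default: return std::pow(x, n);
  }
}

// class parameter bundle unpacked from R
struct ClassPar {
  double Cm, area, Ihold_nA, ca_phi, ca_tau, v_init;
  int nchan;
  std::vector<double> g, E;          // mS/cm2, mV
  std::vector<int> N, M, kid_m, kid_h, ca_mode, is_ca;
};

// Synapse bookkeeping: all idle edges of a projection decay at the same
// rate exp(-beta dt), so their weighted sum per postsynaptic cell is kept as
// one aggregate that decays multiplicatively.  Only edges inside a
// transmitter pulse (C_dur ms after a presynaptic spike) are integrated
// individually; idle edges are synced lazily via a step timestamp when a
// spike retriggers them.
// [[Rcpp::export(name = "cpp_run_network")]]
List cpp_run_network(IntegerVector cell_class,
                     List class_params,
                     IntegerVector e_pre, IntegerVector e_post,
                     NumericVector e_w, IntegerVector e_proj,
                     NumericMatrix proj_par,   // cols: sinf,taus,beta,Cdur,Esyn,receptor,post0,npost
                     double dt, double settle, double record, double record_dt,
                     IntegerVector stim_gid, NumericVector stim_amp,
                     NumericVector stim_on, NumericVector stim_off,
                     IntegerVector vrec_gid, IntegerVector lfprec_gid,
                     double spike_thresh, double refractory, double v_abort) {
  const int ncell = cell_class.size();
  const int nclass = class_params.size();
  const R_xlen_t nedge = e_pre.size();
  const int nproj = proj_par.nrow();

  if (dt <= 0) stop("dt must be positive");
  int m_rec = (int)std::lround(record_dt / dt);
  if (std::fabs(m_rec * dt - record_dt) > 1e-9)
    stop("dt must divide record_dt");

  std::vector<ClassPar> cp(nclass);
  for (int c = 0; c < nclass; ++c) {
    List L = class_params[c];
    ClassPar &p = cp[c];
    p.Cm = as<double>(L["Cm"]);
    p.area = as<double>(L["area"]);
    p.Ihold_nA = as<double>(L["I_hold"]);
    p.ca_phi = as<double>(L["ca_phi"]);
    p.ca_tau = as<double>(L["ca_tau"]);
    p.v_init = as<double>(L["v_init"]);
    NumericMatrix ch = as<NumericMatrix>(L["chan"]);
    p.nchan = ch.nrow();
    for (int k = 0; k < p.nchan; ++k) {
      p.g.push_back(ch(k, 0) * 1000.0);  // S/cm2 -> mS/cm2
      p.E.push_back(ch(k, 1));
      p.N.push_back((int)ch(k, 2));
      p.M.push_back((int)ch(k, 3));
      p.kid_m.push_back((int)ch(k, 4));
      p.kid_h.push_back((int)ch(k, 5));
      p.ca_mode.push_back((int)ch(k, 6));
      p.is_ca.push_back((int)ch(k, 7));
    }
  }

  // gate lookup tables for every kinetics id used
  std::vector<GateTable> tabs(N_KIN);
  std::vector<bool> have(N_KIN, false);
  for (int c = 0; c < nclass; ++c)
    for (int k = 0; k < cp[c].nchan; ++k) {
      int km = cp[c].kid_m[k], kh = cp[c].kid_h[k];
      if (km >= 0 && !have[km]) { build_table(km, dt, tabs[km]); have[km] = true; }
      if (kh >= 0 && !have[kh]) { build_table(kh, dt, tabs[kh]); have[kh] = true; }
    }

  // state
  std::vector<double> V(ncell), Ca(ncell, 0.0), last_spk(ncell, -1e9),
      prevV(ncell);
  std::vector<int> gate_base(ncell + 1, 0);
  for (int i = 0; i < ncell; ++i)
    gate_base[i + 1] = gate_base[i] + 2 * cp[cell_class[i]].nchan;
  std::vector<double> gates(gate_base[ncell]);

  for (int i = 0; i < ncell; ++i) {
    const ClassPar &p = cp[cell_class[i]];
    V[i] = prevV[i] = p.v_init;
    double xi, xt;
    for (int k = 0; k < p.nchan; ++k) {
      double m0 = 1.0, h0 = 1.0;
      if (p.kid_m[k] >= 0) { kin_rates(p.kid_m[k], V[i], xi, xt); m0 = xi; }
      if (p.ca_mode[k] == 2) m0 = 0.0;  // Ca-driven AHP gate starts closed
      if (p.kid_h[k] >= 0) { kin_rates(p.kid_h[k], V[i], xi, xt); h0 = xi; }
      gates[gate_base[i] + 2 * k] = m0;
      gates[gate_base[i] + 2 * k + 1] = h0;
    }
  }

  // synapse state & per-projection constants
  std::vector<double> es(nedge, 0.0), epulse(nedge, 0.0);
  std::vector<long> elast(nedge, 0);
  std::vector<double> psinf(nproj), pef(nproj), pdf(nproj), pcdur(nproj),
      pE(nproj);
  std::vector<int> prec(nproj), ppost0(nproj), pnpost(nproj), agg_off(nproj + 1);
  for (int p = 0; p < nproj; ++p) {
    psinf[p] = proj_par(p, 0);
    pef[p] = std::exp(-dt / proj_par(p, 1));
    pdf[p] = std::exp(-proj_par(p, 2) * dt);
    pcdur[p] = proj_par(p, 3);
    pE[p] = proj_par(p, 4);
    prec[p] = (int)proj_par(p, 5);
    ppost0[p] = (int)proj_par(p, 6);
    pnpost[p] = (int)proj_par(p, 7);
    agg_off[p + 1] = agg_off[p] + pnpost[p];
  }
  std::vector<double> D(agg_off[nproj], 0.0);  // idle-edge aggregates
  std::vector<int> eagg(nedge);
  for (R_xlen_t e = 0; e < nedge; ++e)
    eagg[e] = agg_off[e_proj[e]] + (e_post[e] - ppost0[e_proj[e]]);
  std::vector<int> active;
  active.reserve(4096);
  // out-edge index by presynaptic cell (edges themselves are proj-sorted)
  std::vector<int> pe_idx(nedge), pe_n(ncell + 1, 0);
  for (R_xlen_t e = 0; e < nedge; ++e) pe_n[e_pre[e] + 1]++;
  for (int i = 0; i < ncell; ++i) pe_n[i + 1] += pe_n[i];
  {
    std::vector<int> cur(pe_n.begin(), pe_n.end() - 1);
    for (R_xlen_t e = 0; e < nedge; ++e) pe_idx[cur[e_pre[e]]++] = e;
  }

  // recording buffers
  long nsteps = (long)std::lround((settle + record) / dt);
  long settle_steps = (long)std::lround(settle / dt);
  int nrec = (int)std::lround(record / record_dt);
  NumericMatrix Vrec(nrec, vrec_gid.size());
  NumericMatrix IrecA(nrec, lfprec_gid.size());
  NumericMatrix IrecGA(nrec, lfprec_gid.size());
  NumericMatrix IrecGB(nrec, lfprec_gid.size());
  std::vector<int> spk_gid;
  std::vector<double> spk_t;
  spk_gid.reserve(100000);
  spk_t.reserve(100000);

  std::vector<double> IsynA(ncell), IsynGA(ncell), IsynGB(ncell);

  for (long step = 0; step < nsteps; ++step) {
    double t = step * dt;

    std::fill(IsynA.begin(), IsynA.end(), 0.0);
    std::fill(IsynGA.begin(), IsynGA.end(), 0.0);
    std::fill(IsynGB.begin(), IsynGB.end(), 0.0);

    // idle synapses: aggregate decay + currents (nA) per projection/post cell
    for (int p = 0; p < nproj; ++p) {
      const double df = pdf[p], E = pE[p];
      double *Dp = &D[agg_off[p]];
      double *acc = prec[p] == 0 ? IsynA.data()
                  : prec[p] == 1 ? IsynGA.data() : IsynGB.data();
      const int post0 = ppost0[p], np = pnpost[p];
      for (int j = 0; j < np; ++j) {
        double a = Dp[j] * df;
        Dp[j] = a;
        if (a != 0.0) acc[post0 + j] += a * (V[post0 + j] - E);
      }
    }
    // edges inside a transmitter pulse: individual exact-exponential update
    for (size_t ai = 0; ai < active.size();) {
      int e = active[ai];
      int p = e_proj[e];
      double s = psinf[p] + (es[e] - psinf[p]) * pef[p];
      es[e] = s;
      epulse[e] -= dt;
      int post = e_post[e];
      double I = e_w[e] * s * (V[post] - pE[p]);  // uS*mV = nA
      switch (prec[p]) {
      case 0: IsynA[post] += I; break;
      case 1: IsynGA[post] += I; break;
      default: IsynGB[post] += I; break;
      }
      if (epulse[e] <= 0.0) {   // pulse over: hand the edge back to its aggregate
        D[eagg[e]] += e_w[e] * s;
        elast[e] = step;
        active[ai] = active.back();
        active.pop_back();
      } else {
        ++ai;
      }
    }

    // record (state at time t, currents just computed)
    if (step >= settle_steps && (step - settle_steps) % m_rec == 0) {
      int ridx = (int)((step - settle_steps) / m_rec);
      if (ridx < nrec) {
        for (int j = 0; j < vrec_gid.size(); ++j)
          Vrec(ridx, j) = V[vrec_gid[j]];
        for (int j = 0; j < lfprec_gid.size(); ++j) {
          int g = lfprec_gid[j];
          IrecA(ridx, j) = IsynA[g];
          IrecGA(ridx, j) = IsynGA[g];
          IrecGB(ridx, j) = IsynGB[g];
        }
      }
    }

    // membrane + gates + calcium
    for (int i = 0; i < ncell; ++i) {
      const ClassPar &p = cp[cell_class[i]];
      int gb = gate_base[i];
      double v = V[i];
      double Iion = 0.0, Ica = 0.0;  // uA/cm2
      for (int k = 0; k < p.nchan; ++k) {
        double cur = p.g[k];
        if (cur == 0.0) continue;
        double m = gates[gb + 2 * k], h = gates[gb + 2 * k + 1];
        if (p.kid_m[k] >= 0 || p.ca_mode[k] == 2) cur *= ipow(m, p.N[k]);
        if (p.kid_h[k] >= 0) cur *= ipow(h, p.M[k]);
        cur *= (v - p.E[k]);
        if (p.ca_mode[k] == 1) {
          double f = Ca[i] / 250.0;
          cur *= (f < 1.0 ? f : 1.0);
        }
        Iion += cur;
        if (p.is_ca[k]) Ica += cur;
      }
      double Iext_nA = p.Ihold_nA;
      for (int si = 0; si < stim_gid.size(); ++si)
        if (stim_gid[si] == i && t >= stim_on[si] && t < stim_off[si])
          Iext_nA += stim_amp[si];
      double Isyn_dens =
          (IsynA[i] + IsynGA[i] + IsynGB[i]) / p.area / 1000.0;  // uA/cm2
      double Iext_dens = Iext_nA / p.area / 1000.0;
      double vnew = v + dt * (Iext_dens - Iion - Isyn_dens) / p.Cm;

      if (!std::isfinite(vnew) || std::fabs(vnew) > v_abort)
        stop("numerical blow-up: cell %d (class %d) at t = %.3f ms, V = %g",
             i, (int)cell_class[i], t, vnew);

      // gates (exact-exponential via tables, at voltage v)
      double fj = (v - V_TAB_MIN) / V_TAB_DV;
      int j0 = (int)fj;
      if (j0 < 0) { j0 = 0; fj = 0.0; }
      if (j0 >= V_TAB_N - 1) { j0 = V_TAB_N - 2; fj = (double)(V_TAB_N - 1); }
      double w1 = fj - j0, w0 = 1.0 - w1;
      for (int k = 0; k < p.nchan; ++k) {
        int km = p.kid_m[k], kh = p.kid_h[k];
        if (km >= 0) {
          const GateTable &tb = tabs[km];
          double xinf = w0 * tb.inf[j0] + w1 * tb.inf[j0 + 1];
          double ef = w0 * tb.efac[j0] + w1 * tb.efac[j0 + 1];
          gates[gb + 2 * k] += (xinf - gates[gb + 2 * k]) * ef;
        } else if (p.ca_mode[k] == 2) {
          double a = 2e-5 * Ca[i];
          if (a > 0.01) a = 0.01;
          double bq = 0.001, sab = a + bq;
          gates[gb + 2 * k] +=
              (a / sab - gates[gb + 2 * k]) * dt * sab;
        }
        if (kh >= 0) {
          const GateTable &tb = tabs[kh];
          double xinf = w0 * tb.inf[j0] + w1 * tb.inf[j0 + 1];
          double ef = w0 * tb.efac[j0] + w1 * tb.efac[j0 + 1];
          gates[gb + 2 * k + 1] += (xinf - gates[gb + 2 * k + 1]) * ef;
        }
      }

      // calcium pool driven by inward Ca currents
      if (p.ca_phi > 0.0) {
        Ca[i] += dt * (-p.ca_phi * Ica - Ca[i] / p.ca_tau);
        if (Ca[i] < 0.0) Ca[i] = 0.0;
      }

      // spike detection on the updated voltage
      if (vnew >= spike_thresh && v < spike_thresh &&
          (t + dt) - last_spk[i] >= refractory) {
        last_spk[i] = t + dt;
        spk_gid.push_back(i);
        spk_t.push_back(t + dt);
        for (int q = pe_n[i]; q < pe_n[i + 1]; ++q) {
          int e = pe_idx[q];
          int p = e_proj[e];
          if (epulse[e] <= 0.0) {  // idle: sync lazy decay, detach from aggregate
            es[e] *= std::pow(pdf[p], (double)(step - elast[e]));
            elast[e] = step;
            D[eagg[e]] -= e_w[e] * es[e];
            active.push_back(e);
          }
          epulse[e] = pcdur[p];  // retrigger: reset pulse clock, keep s(t0)
        }
      }
      V[i] = vnew;
    }
  }

  return List::create(
      _["V"] = Vrec, _["isyn_ampa"] = IrecA, _["isyn_gabaa"] = IrecGA,
      _["isyn_gabab"] = IrecGB,
      _["spike_gid"] = IntegerVector(spk_gid.begin(), spk_gid.end()),
      _["spike_t"] = NumericVector(spk_t.begin(), spk_t.end()));
}
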
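// 1D arterial network solver.
//
// Finite-volume Richtmyer (two-step Lax-Wendroff) discretization of the
// area-flow (A,Q) equations with an Olufsen-type pressure-area law
//   p = f0 (1 - sqrt(A0/A)),   f0 = (4/3) Eh/r0,
// written in conservative form with the well-balanced momentum flux
//   F2 = Q^2/A + B,  B = (f0/rho)(sqrt(A0 A) - A0),
// whose geometric source vanishes identically at rest (A = A0), so tapered
// segments hold equilibrium exactly.  Boundary faces take their fluxes from
// characteristic solves: prescribed-flow or elastance-ventricle inflow at
// the root, total-pressure/mass Newton solves at junctions, RCR Windkessel
// terminals at leaves.  Mass is conserved to round-off by construction.
//
// All quantities CGS (cm, g, s, dyn/cm^2); unit conversions live in R.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// avoid libm fmod (glibc symbol versioning)
inline double wrapT(double t, double T) {
  double r = t - T * std::floor(t / T);
  return (r < 0) ? r + T : r;
}

inline double pres(double A, double A0, double f0) {
  return f0 * (1.0 - std::sqrt(A0 / A));
}
inline double dpdA(double A, double A0, double f0) {
  return 0.5 * f0 * std::sqrt(A0) / (A * std::sqrt(A));
}
inline double wspeed(double A, double A0, double f0, double rho) {
  // c^2 = (A/rho) dp/dA = (f0/(2 rho)) sqrt(A0/A)
  return std::sqrt(0.5 * f0 / rho * std::sqrt(A0 / A));
}

// Riemann invariants for this tube law: the forward characteristic
// (dx/dt = u + c) carries W+ = u - 4c, the backward one W- = u + 4c.

struct Elastance {
  double Emax, Emin, tm, T, plat_frac, relax_frac;
  double operator()(double t) const {
    double tt = wrapT(t, T);
    const double t_plat = plat_frac * T, t_rel = relax_frac * T;
    if (tt < tm)
      return Emin + 0.5 * (Emax - Emin) * (1.0 - std::cos(M_PI * tt / tm));
    if (tt < tm + t_plat) return Emax;
    if (tt < tm + t_plat + t_rel)
      return Emin + 0.5 * (Emax - Emin) *
                        (1.0 + std::cos(M_PI * (tt - tm - t_plat) / t_rel));
    return Emin;
  }
};

// small dense linear solve (Gaussian elimination, partial pivot)
bool lsolve(double* M, double* b, int n) {
  for (int k = 0; k < n; ++k) {
    int piv = k;
    double best = std::fabs(M[k * n + k]);
    for (int i = k + 1; i < n; ++i) {
      double v = std::fabs(M[i * n + k]);
      if (v > best) { best = v; piv = i; }
    }
    if (best < 1e-14) return false;
    if (piv != k) {
      for (int j = 0; j < n; ++j) std::swap(M[k * n + j], M[piv * n + j]);
      std::swap(b[k], b[piv]);
    }
    for (int i = k + 1; i < n; ++i) {
      double f = M[i * n + k] / M[k * n + k];
      if (f == 0.0) continue;
      for (int j = k; j < n; ++j) M[i * n + j] -= f * M[k * n + j];
      b[i] -= f * b[k];
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    for (int j = i + 1; j < n; ++j) s -= M[i * n + j] * b[j];
    b[i] = s / M[i * n + i];
  }
  return true;
}

struct Segment {
  int n;                          // cells
  double dx;
  // cell-centred geometry
  std::vector<double> A0, f0, A0x, f0x;
  // interface geometry (n+1 faces; 0 and n are the segment ends)
  std::vector<double> A0h, f0h;
  // cached constants: sqrt(A0) at cells/faces, wave-speed factor
  // sqrt(f0/(2 rho)) at cells
  std::vector<double> sqA0, sqA0h, cfac;
  // state
  std::vector<double> A, Q;
  std::vector<double> FA, FQ;     // face fluxes (n+1)
  std::vector<double> sA, F2c, lamc;  // per-step scratch (cells)
  // boundary states (from the characteristic solves)
  double AL = 0, QL = 0, AR = 0, QR = 0;
  int parent;                     // -1 for root
  std::vector<int> children;
  bool has_term = false;
  double R1 = 0, R2 = 0, C = 0, pc = 0;
};

struct Network {
  std::vector<Segment> S;
  int root = -1;
  double rho = 1.06, Kr = 0.0, p_ven = 0.0;
  double eps_visc = 0.05;  // Rusanov blend; damps odd-even null modes
  bool failed = false;

  inline double flux2(double A, double Q, double A0, double f0) const {
    return Q * Q / A + (f0 / rho) * (std::sqrt(A0 * A) - A0);
  }
  // geometric + friction source; vanishes at A = A0, Q = 0
  inline double src(double A, double Q, double A0, double f0, double A0x,
                    double f0x) const {
    return (f0x / rho) * (2.0 * std::sqrt(A0 * A) - A0 - A) +
           (f0 * A0x / rho) * (std::sqrt(A / A0) - 1.0) - Kr * Q / A;
  }

  // characteristic invariants extrapolated to the segment ends; the foot
  // of the characteristic is interpolated between the (old) boundary state
  // and the first/last cell centre, half a cell away.
  double Wminus(const Segment& g, double dt) const {
    double u0 = g.Q[0] / g.A[0];
    double c0 = wspeed(g.A[0], g.A0[0], g.f0[0], rho);
    double w = std::min(1.0, std::max(0.0, (c0 - u0) * dt / (0.5 * g.dx)));
    double Af = (1 - w) * g.AL + w * g.A[0];
    double Qf = (1 - w) * g.QL + w * g.Q[0];
    return Qf / Af + 4.0 * wspeed(Af, g.A0h[0], g.f0h[0], rho);
  }
  double Wplus(const Segment& g, double dt) const {
    const int n = g.n;
    double u1 = g.Q[n - 1] / g.A[n - 1];
    double c1 = wspeed(g.A[n - 1], g.A0[n - 1], g.f0[n - 1], rho);
    double w = std::min(1.0, std::max(0.0, (u1 + c1) * dt / (0.5 * g.dx)));
    double Af = (1 - w) * g.AR + w * g.A[n - 1];
    double Qf = (1 - w) * g.QR + w * g.Q[n - 1];
    return Qf / Af - 4.0 * wspeed(Af, g.A0h[n], g.f0h[n], rho);
  }

  void inlet_bc(double Qin, double dt) {
    Segment& g = S[root];
    double Wm = Wminus(g, dt);
    double A = g.AL;
    for (int k = 0; k < 12; ++k) {
      double c = wspeed(A, g.A0h[0], g.f0h[0], rho);
      double fn = Qin / A + 4.0 * c - Wm;
      double df = -Qin / (A * A) - c / A;
      double step = fn / df;
      A -= step;
      if (A <= 0.2 * g.A0h[0]) A = 0.2 * g.A0h[0];
      if (std::fabs(step) < 1e-12 * g.A0h[0]) break;
    }
    g.AL = A; g.QL = Qin;
    g.FA[0] = Qin;
    g.FQ[0] = flux2(A, Qin, g.A0h[0], g.f0h[0]);
  }

  double terminal_bc(Segment& g, double dt) {
    const int n = g.n;
    double Wp = Wplus(g, dt);
    double A = g.AR;
    double pc = (g.C > 0.0) ? g.pc : p_ven;
    const double A0b = g.A0h[n], f0b = g.f0h[n];
    for (int k = 0; k < 12; ++k) {
      double c = wspeed(A, A0b, f0b, rho);
      double u = Wp + 4.0 * c;
      double h = pres(A, A0b, f0b) - g.R1 * A * u - pc;
      double dh = dpdA(A, A0b, f0b) - g.R1 * (u - c);
      double step = h / dh;
      A -= step;
      if (A <= 0.2 * A0b) A = 0.2 * A0b;
      if (std::fabs(step) < 1e-12 * A0b) break;
    }
    double c = wspeed(A, A0b, f0b, rho);
    double Qend = A * (Wp + 4.0 * c);
    g.AR = A; g.QR = Qend;
    g.FA[n] = Qend;
    g.FQ[n] = flux2(A, Qend, A0b, f0b);
    if (g.C > 0.0) g.pc += dt * (Qend - (g.pc - p_ven) / g.R2) / g.C;
    return Qend;
  }

  // coupled parent-outlet / child-inlet solve: parent forward invariant,
  // child backward invariants, conservation of mass, continuity of total
  // pressure p + rho u^2 / 2.
  void junction_bc(Segment& gp, double dt) {
    const int nc = (int)gp.children.size();
    const int np = gp.n;
    double Wp = Wplus(gp, dt);
    std::vector<double> Wm(nc);
    for (int j = 0; j < nc; ++j) Wm[j] = Wminus(S[gp.children[j]], dt);
    const int m = 2 + 2 * nc;  // at most 6 (bifurcation)
    double x[6], F[6], J[36];
    x[0] = gp.AR; x[1] = gp.QR;
    for (int j = 0; j < nc; ++j) {
      Segment& gc = S[gp.children[j]];
      x[2 + 2 * j] = gc.AL; x[3 + 2 * j] = gc.QL;
    }
    const double A0p = gp.A0h[np], f0p = gp.f0h[np];
    for (int iter = 0; iter < 15; ++iter) {
      for (int i = 0; i < m; ++i) F[i] = 0.0;
      for (int i = 0; i < m * m; ++i) J[i] = 0.0;
      double Apar = x[0], Qpar = x[1];
      double cP = wspeed(Apar, A0p, f0p, rho);
      F[0] = Qpar / Apar - 4.0 * cP - Wp;
      J[0 * m + 0] = -Qpar / (Apar * Apar) + cP / Apar;
      J[0 * m + 1] = 1.0 / Apar;
      F[1] = Qpar;
      J[1 * m + 1] = 1.0;
      for (int j = 0; j < nc; ++j) {
        F[1] -= x[3 + 2 * j];
        J[1 * m + (3 + 2 * j)] = -1.0;
      }
      double ptp =
          pres(Apar, A0p, f0p) + 0.5 * rho * (Qpar / Apar) * (Qpar / Apar);
      for (int j = 0; j < nc; ++j) {
        Segment& gc = S[gp.children[j]];
        double Ac = x[2 + 2 * j], Qc = x[3 + 2 * j];
        double A0c = gc.A0h[0], f0c = gc.f0h[0];
        double cC = wspeed(Ac, A0c, f0c, rho);
        int r1 = 2 + 2 * j;
        F[r1] = Qc / Ac + 4.0 * cC - Wm[j];
        J[r1 * m + (2 + 2 * j)] = -Qc / (Ac * Ac) - cC / Ac;
        J[r1 * m + (3 + 2 * j)] = 1.0 / Ac;
        int r2 = 3 + 2 * j;
        double ptc = pres(Ac, A0c, f0c) + 0.5 * rho * (Qc / Ac) * (Qc / Ac);
        F[r2] = ptp - ptc;
        J[r2 * m + 0] =
            dpdA(Apar, A0p, f0p) - rho * Qpar * Qpar / (Apar * Apar * Apar);
        J[r2 * m + 1] = rho * Qpar / (Apar * Apar);
        J[r2 * m + (2 + 2 * j)] =
            -(dpdA(Ac, A0c, f0c) - rho * Qc * Qc / (Ac * Ac * Ac));
        J[r2 * m + (3 + 2 * j)] = -rho * Qc / (Ac * Ac);
      }
      if (!lsolve(J, F, m)) { failed = true; return; }
      double mx = 0.0;
      for (int i = 0; i < m; ++i) {
        x[i] -= F[i];
        mx = std::max(mx, std::fabs(F[i]));
      }
      if (x[0] < 0.2 * A0p) x[0] = 0.2 * A0p;
      for (int j = 0; j < nc; ++j)
        if (x[2 + 2 * j] < 0.2 * S[gp.children[j]].A0h[0])
          x[2 + 2 * j] = 0.2 * S[gp.children[j]].A0h[0];
      if (mx < 1e-10 * (1.0 + std::fabs(x[0]))) break;
    }
    gp.AR = x[0]; gp.QR = x[1];
    gp.FA[np] = gp.QR;
    gp.FQ[np] = flux2(gp.AR, gp.QR, A0p, f0p);
    for (int j = 0; j < nc; ++j) {
      Segment& gc = S[gp.children[j]];
      gc.AL = x[2 + 2 * j]; gc.QL = x[3 + 2 * j];
      gc.FA[0] = gc.QL;
      gc.FQ[0] = flux2(gc.AL, gc.QL, gc.A0h[0], gc.f0h[0]);
    }
  }

  // Richtmyer half-step states at interior faces -> face fluxes
  void interior_fluxes(Segment& g, double dt) {
    const int n = g.n;
    const double r = dt / g.dx;
    // per-cell caches: sqrt(A), momentum flux, local wave speed
    for (int i = 0; i < n; ++i) {
      double sa = std::sqrt(g.A[i]);
      g.sA[i] = sa;
      g.F2c[i] = g.Q[i] * g.Q[i] / g.A[i] +
                 (g.f0[i] / rho) * (g.sqA0[i] * sa - g.A0[i]);
      // c = cfac * (A0/A)^{1/4} = cfac * sqrt(sqA0/sA)
      g.lamc[i] = std::fabs(g.Q[i] / g.A[i]) +
                  g.cfac[i] * std::sqrt(g.sqA0[i] / sa);
    }
    for (int i = 1; i < n; ++i) {
      double Am = 0.5 * (g.A[i - 1] + g.A[i]);
      double Qm = 0.5 * (g.Q[i - 1] + g.Q[i]);
      double dF1 = g.Q[i] - g.Q[i - 1];
      double dF2 = g.F2c[i] - g.F2c[i - 1];
      double A0x = (g.A0[i] - g.A0[i - 1]) / g.dx;
      double f0x = (g.f0[i] - g.f0[i - 1]) / g.dx;
      double Ah = Am - 0.5 * r * dF1;
      double sAm = std::sqrt(Am);
      double srcm = (f0x / rho) * (2.0 * g.sqA0h[i] * sAm - g.A0h[i] - Am) +
                    (g.f0h[i] * A0x / rho) * (sAm / g.sqA0h[i] - 1.0) -
                    Kr * Qm / Am;
      double Qh = Qm - 0.5 * r * dF2 + 0.5 * dt * srcm;
      if (!(Ah > 0.0) || !R_finite(Ah)) { failed = true; return; }
      // small upwind-type dissipation on the deviation from equilibrium
      // (keeps the rest state exact); removes the odd-even null mode of
      // the two-step Lax-Wendroff scheme
      double lam = std::max(g.lamc[i - 1], g.lamc[i]);
      double dAdev = (g.A[i] - g.A0[i]) - (g.A[i - 1] - g.A0[i - 1]);
      double sAh = std::sqrt(Ah);
      g.FA[i] = Qh - eps_visc * lam * dAdev;
      g.FQ[i] = Qh * Qh / Ah +
                (g.f0h[i] / rho) * (g.sqA0h[i] * sAh - g.A0h[i]) -
                eps_visc * lam * (g.Q[i] - g.Q[i - 1]);
    }
  }

  void update_cells(Segment& g, double dt) {
    const int n = g.n;
    const double r = dt / g.dx;
    for (int i = 0; i < n; ++i) {
      double An = g.A[i] - r * (g.FA[i + 1] - g.FA[i]);
      double sa = g.sA[i];
      double srci =
          (g.f0x[i] / rho) * (2.0 * g.sqA0[i] * sa - g.A0[i] - g.A[i]) +
          (g.f0[i] * g.A0x[i] / rho) * (sa / g.sqA0[i] - 1.0) -
          Kr * g.Q[i] / g.A[i];
      double Qn = g.Q[i] - r * (g.FQ[i + 1] - g.FQ[i]) + dt * srci;
      g.A[i] = An; g.Q[i] = Qn;
      if (!(An > 0.0) || !R_finite(An)) { failed = true; return; }
    }
  }

  // advance the network by dt with prescribed root inflow Qin
  void step(double Qin, double dt, std::vector<double>& term_out) {
    for (auto& g : S) {
      interior_fluxes(g, dt);
      if (failed) return;
    }
    inlet_bc(Qin, dt);
    for (size_t s = 0; s < S.size(); ++s)
      if (S[s].has_term) term_out[s] += terminal_bc(S[s], dt);
    for (auto& g : S)
      if (!g.children.empty()) {
        junction_bc(g, dt);
        if (failed) return;
      }
    for (auto& g : S) {
      update_cells(g, dt);
      if (failed) return;
    }
  }

  double root_pressure() const {
    const Segment& g = S[root];
    return pres(g.AL, g.A0h[0], g.f0h[0]);
  }

  double max_cfl(double dt) const {
    double worst = 0.0;
    for (const auto& g : S)
      for (int i = 0; i < g.n; ++i) {
        double lam = std::fabs(g.Q[i] / g.A[i]) +
                     wspeed(g.A[i], g.A0[i], g.f0[i], rho);
        worst = std::max(worst, lam * dt / g.dx);
      }
    return worst;
  }
};

}  // namespace

// [[Rcpp::export]]
double elastance_cpp(double t, double Emax, double Emin, double tm, double T,
                     double plat_frac, double relax_frac) {
  Elastance E{Emax, Emin, tm, T, plat_frac, relax_frac};
  return E(t);
}

// [[Rcpp::export]]
List solve_network_cpp(List tree, List lv, List cfg) {
  NumericVector len = tree["length"], rp = tree["r_prox"], rd = tree["r_dist"];
  IntegerVector parent = tree["parent"];  // 0-based, -1 root
  NumericVector tR1 = tree["term_R1"], tR2 = tree["term_R2"],
                tC = tree["term_C"];
  const double k1 = tree["k1"], k2 = tree["k2"], k3 = tree["k3"];
  const int nseg = len.size();

  const double rho = cfg["rho"], mu = cfg["mu"];
  const double dx_target = cfg["dx_target"], cfl = cfg["cfl"];
  const int max_cycles = cfg["max_cycles"];
  const double tol = cfg["tol"];
  const double p_init = cfg["p_init"], p_ven = cfg["p_ven"];
  NumericVector inflow = cfg["inflow"];  // sampled over one period, or empty
  const bool use_lv = inflow.size() == 0;
  const int max_attempts = cfg.containsElementNamed("attempts")
                               ? (int)cfg["attempts"] : 3;
  // optional subset of segments whose full fields are stored (0-based);
  // empty means all
  std::vector<bool> store_seg;
  if (cfg.containsElementNamed("store_idx")) {
    IntegerVector si = cfg["store_idx"];
    if (si.size() > 0) {
      store_seg.assign(nseg, false);
      for (int i = 0; i < si.size(); ++i)
        if (si[i] >= 0 && si[i] < nseg) store_seg[si[i]] = true;
    }
  }
  if (store_seg.empty()) store_seg.assign(nseg, true);

  const double T = lv["T"];
  Elastance E{lv["Emax"], lv["Emin"], lv["tm"], T,
              lv["plat_frac"], lv["relax_frac"]};
  const double pla = lv["pla"], V0 = lv["V0"];
  const double Rmv = lv["Rmv"], Rav = lv["Rav"];

  // optional reference stiffness for the time-step bound: keeps the step
  // count independent of the tuned k3, so the objective stays smooth in
  // the parameters during fitting
  const double k3_ref = cfg.containsElementNamed("k3_ref")
                            ? (double)cfg["k3_ref"] : k3;
  Network net;
  net.rho = rho;
  net.Kr = 2.0 * M_PI * (9.0 + 2.0) * (mu / rho);  // flat-core profile
  net.p_ven = p_ven;
  net.eps_visc = cfg["visc"];
  net.S.resize(nseg);
  double dt_bound = 1e30;
  auto ehr = [&](double r0) {
    return (4.0 / 3.0) * (k1 * std::exp(k2 * r0) + k3);
  };
  for (int s = 0; s < nseg; ++s) {
    Segment& g = net.S[s];
    g.parent = parent[s];
    if (g.parent < 0) net.root = s;
    else net.S[g.parent].children.push_back(s);
    g.n = std::max(2, (int)std::lround(len[s] / dx_target));  // >= 1 interior face
    g.dx = len[s] / g.n;
    g.A0.resize(g.n); g.f0.resize(g.n);
    g.A0x.resize(g.n); g.f0x.resize(g.n);
    g.A0h.resize(g.n + 1); g.f0h.resize(g.n + 1);
    g.A.resize(g.n); g.Q.resize(g.n);
    g.FA.resize(g.n + 1); g.FQ.resize(g.n + 1);
    g.sqA0.resize(g.n); g.sqA0h.resize(g.n + 1); g.cfac.resize(g.n);
    g.sA.resize(g.n); g.F2c.resize(g.n); g.lamc.resize(g.n);
    double cmax_s = 0.0;
    for (int i = 0; i < g.n; ++i) {  // cell centres
      double x = (i + 0.5) / g.n;
      double r0 = rp[s] + (rd[s] - rp[s]) * x;
      g.A0[i] = M_PI * r0 * r0;
      g.f0[i] = ehr(r0);
      double f0r = (4.0 / 3.0) * (k1 * std::exp(k2 * r0) + k3_ref);
      cmax_s = std::max(cmax_s, wspeed(g.A0[i], g.A0[i],
                                       std::max(g.f0[i], f0r), rho));
    }
    // end faces exact, interior faces averaged (keeps the rest state an
    // exact discrete equilibrium)
    g.A0h[0] = M_PI * rp[s] * rp[s];  g.f0h[0] = ehr(rp[s]);
    g.A0h[g.n] = M_PI * rd[s] * rd[s]; g.f0h[g.n] = ehr(rd[s]);
    for (int i = 1; i < g.n; ++i) {
      g.A0h[i] = 0.5 * (g.A0[i - 1] + g.A0[i]);
      g.f0h[i] = 0.5 * (g.f0[i - 1] + g.f0[i]);
    }
    for (int i = 0; i < g.n; ++i) {
      g.A0x[i] = (g.A0h[i + 1] - g.A0h[i]) / g.dx;
      g.f0x[i] = (g.f0h[i + 1] - g.f0h[i]) / g.dx;
      g.sqA0[i] = std::sqrt(g.A0[i]);
      g.cfac[i] = std::sqrt(0.5 * g.f0[i] / rho);
    }
    for (int i = 0; i <= g.n; ++i) g.sqA0h[i] = std::sqrt(g.A0h[i]);
    dt_bound = std::min(dt_bound, g.dx / (cmax_s * 1.15 + 150.0));
    if (R_finite(tR1[s])) {
      g.has_term = true;
      g.R1 = tR1[s]; g.R2 = tR2[s]; g.C = tC[s];
    }
  }
  if (net.root < 0) stop("no root segment");

  const double Vlv0 = V0 + pla / E(0.0);  // filled to atrial pressure
  double Vlv = Vlv0;

  auto reset_state = [&](void) {
    for (auto& g : net.S) {
      for (int i = 0; i < g.n; ++i) {
        double sq = 1.0 - p_init / g.f0[i];
        g.A[i] = g.A0[i] / (sq * sq);
        g.Q[i] = 0.0;
      }
      double sqL = 1.0 - p_init / g.f0h[0];
      double sqR = 1.0 - p_init / g.f0h[g.n];
      g.AL = g.A0h[0] / (sqL * sqL); g.QL = 0.0;
      g.AR = g.A0h[g.n] / (sqR * sqR); g.QR = 0.0;
      if (g.has_term) g.pc = p_init;
    }
    Vlv = Vlv0;
    net.failed = false;
  };

  int steps = (int)std::ceil(T / (cfl * dt_bound));
  double dt = T / steps;

  std::vector<double> term_out(nseg, 0.0);
  double residual = NA_REAL;
  int cycles_run = 0;
  bool converged = false;
  double cfl_max_seen = 0.0;
  std::vector<double> proot_prev, proot_cur;

  for (int attempt = 0; attempt < max_attempts; ++attempt) {
    if (attempt > 0) { steps *= 2; dt = T / steps; }
    reset_state();
    proot_prev.assign(steps, 0.0); proot_cur.assign(steps, 0.0);
    converged = false; cycles_run = 0;
    bool bad = false;

    for (int cyc = 0; cyc < max_cycles && !bad; ++cyc) {
      std::fill(term_out.begin(), term_out.end(), 0.0);
      for (int it = 0; it < steps; ++it) {
        const double t = it * dt;
        double Qin;
        if (use_lv) {
          double plv = E(t) * (Vlv - V0);
          double proot = net.root_pressure();
          double Qmv = (pla - plv) > 0 ? (pla - plv) / Rmv : 0.0;
          double Qav = (plv - proot) > 0 ? (plv - proot) / Rav : 0.0;
          Vlv += dt * (Qmv - Qav);
          Qin = Qav;
        } else {
          double tau = wrapT(t, T) / T * inflow.size();
          int i0 = (int)tau % inflow.size();
          int i1 = (i0 + 1) % inflow.size();
          double w = tau - std::floor(tau);
          Qin = (1 - w) * inflow[i0] + w * inflow[i1];
        }
        net.step(Qin, dt, term_out);
        if (net.failed) { bad = true; break; }
        proot_cur[it] = net.root_pressure();
        if ((it & 15) == 0) {
          double c = net.max_cfl(dt);
          cfl_max_seen = std::max(cfl_max_seen, c);
          if (c > 1.0) { bad = true; break; }
        }
      }
      if (bad) break;
      cycles_run = cyc + 1;
      double num = 0.0, den = 0.0;
      for (int it = 0; it < steps; ++it) {
        double d = proot_cur[it] - proot_prev[it];
        num += d * d; den += proot_cur[it] * proot_cur[it];
      }
      residual = std::sqrt(num / (den + 1e-300));
      std::swap(proot_cur, proot_prev);
      // tol <= 0 requests a fixed number of cycles (smooth objective for
      // finite-difference Jacobians); convergence is then not tested
      if (tol > 0 && cyc > 0 && residual < tol) { converged = true; break; }
    }
    if (tol <= 0 && cycles_run == max_cycles) converged = true;
    if (!bad) break;
    if (attempt == max_attempts - 1)
      stop("solver unstable even after time-step refinement");
  }

  // ---- one further cycle, storing the full solution ----
  NumericVector Qin_tr(steps), Vlv_tr(steps), t_tr(steps);
  std::vector<NumericMatrix> Am(nseg), Qm(nseg);
  for (int s = 0; s < nseg; ++s) {
    if (!store_seg[s]) continue;
    Am[s] = NumericMatrix(net.S[s].n, steps);
    Qm[s] = NumericMatrix(net.S[s].n, steps);
  }
  std::fill(term_out.begin(), term_out.end(), 0.0);
  double inflow_mean = 0.0;
  for (int it = 0; it < steps; ++it) {
    const double t = it * dt;
    double Qin;
    if (use_lv) {
      double plv = E(t) * (Vlv - V0);
      double proot = net.root_pressure();
      double Qmv = (pla - plv) > 0 ? (pla - plv) / Rmv : 0.0;
      double Qav = (plv - proot) > 0 ? (plv - proot) / Rav : 0.0;
      Vlv += dt * (Qmv - Qav);
      Qin = Qav;
    } else {
      double tau = wrapT(t, T) / T * inflow.size();
      int i0 = (int)tau % inflow.size();
      int i1 = (i0 + 1) % inflow.size();
      double w = tau - std::floor(tau);
      Qin = (1 - w) * inflow[i0] + w * inflow[i1];
    }
    Qin_tr[it] = Qin; Vlv_tr[it] = Vlv; t_tr[it] = t;
    inflow_mean += Qin;
    net.step(Qin, dt, term_out);
    if (net.failed) stop("solver failed during the stored cycle");
    for (int s = 0; s < nseg; ++s) {
      if (!store_seg[s]) continue;
      for (int i = 0; i < net.S[s].n; ++i) {
        Am[s](i, it) = net.S[s].A[i];
        Qm[s](i, it) = net.S[s].Q[i];
      }
    }
  }
  inflow_mean /= steps;

  List segA(nseg), segQ(nseg), segx(nseg), segA0(nseg), segf0(nseg);
  NumericVector term_mean(nseg);
  for (int s = 0; s < nseg; ++s) {
    term_mean[s] = net.S[s].has_term ? term_out[s] / steps : NA_REAL;
    segA[s] = Am[s]; segQ[s] = Qm[s];
    NumericVector xv(net.S[s].n), a0(net.S[s].n), f0v(net.S[s].n);
    for (int i = 0; i < net.S[s].n; ++i) {
      xv[i] = (i + 0.5) * net.S[s].dx;  // cell centres
      a0[i] = net.S[s].A0[i];
      f0v[i] = net.S[s].f0[i];
    }
    segx[s] = xv; segA0[s] = a0; segf0[s] = f0v;
  }

  return List::create(
      _["converged"] = converged, _["cycles"] = cycles_run,
      _["residual"] = residual, _["dt"] = dt, _["steps"] = steps,
      _["t"] = t_tr, _["A"] = segA, _["Q"] = segQ, _["x"] = segx,
      _["A0"] = segA0, _["f0"] = segf0, _["Qin"] = Qin_tr,
      _["Vlv"] = Vlv_tr, _["term_outflow_mean"] = term_mean,
      _["inflow_mean"] = inflow_mean, _["cfl_max"] = cfl_max_seen,
      _["cfl_violated"] = false);
}
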
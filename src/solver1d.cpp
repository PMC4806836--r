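// One-dimensional blood-flow solver over a bifurcating arterial tree.
//
// Governing equations (CGS units throughout):
//   A_t + Q_x = 0
//   Q_t + (Q^2/A + beta A^{3/2} / (3 rho A0))_x = S(A, Q, x)
// with the elastic tube law p = beta (sqrt(A) - sqrt(A0)) / A0, Poiseuille
// friction, and geometric source terms from the reference-area taper.
// Interior scheme: Richtmyer two-step Lax-Wendroff. Kelvin-Voigt wall
// viscosity is treated by operator splitting as an implicit diffusion step
// on Q (Thomas solve per segment). Boundaries are coupled through Riemann
// invariants W = u +/- 4c (c ~ A^{1/4} for this tube law): a lumped
// elastance heart with diode valves at the root, Newton junction solves
// enforcing mass and total-pressure continuity at bifurcations, and RCR
// Windkessel loads at the leaves.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdio>
using namespace Rcpp;

static const double MMHG = 1333.22387415;

struct Segment {
  int n;
  double dx;
  double beta;
  double gamma;
  std::vector<double> A0, dA0, A0h, dA0h; // node and midpoint reference areas
  std::vector<double> A, Q, Aold, Qold;
  std::vector<double> Ah, Qh, F2h; // half-step scratch
  int parent;     // -1 for root
};

struct Terminal {
  int seg;
  double R1, R2, C, pven;
  double pc;     // compliance pressure state
  double vol;    // outflow volume accumulator (per cycle)
  double Q;      // last outflow
};

struct Junction {
  int parent;
  int child[2];
  int nchild;
};

struct Heart {
  double Emax, Emin, V0, T, tact, ppre, Rav, Lav, Rmit;
  double h_t1, h_n1, h_t2, h_n2; // double-Hill shape constants
  double s_peak, shape_max;
  double V, Qav;
};

static inline double hill_shape(double s, double t1, double n1,
                                double t2, double n2) {
  double a = std::pow(s / t1, n1);
  return (a / (1.0 + a)) / (1.0 + std::pow(s / t2, n2));
}

static inline double p_el(double A, double A0, double beta) {
  return beta * (std::sqrt(A) - std::sqrt(A0)) / A0;
}

// wave speed of the elastic branch
static inline double wspeed(double A, double A0, double beta, double rho) {
  return std::sqrt(beta * std::sqrt(A) / (2.0 * rho * A0));
}

struct Model {
  std::vector<Segment> segs;
  std::vector<Terminal> terms;
  std::vector<Junction> juncs;
  double rho, mu;
  double junc_resid;     // max relative mass defect seen at junctions
};

// ---- boundary characteristic extrapolation -------------------------------

// W2 = u - 4c extrapolated to the inlet node (x = 0) along dx/dt = u - c,
// including the friction source along the characteristic (removes an O(dx)
// bias in steady pressure at the boundary node)
static double extrap_W2(const Segment& s, double dt, double rho, double mu) {
  double u0 = s.Qold[0] / s.Aold[0];
  double c0 = wspeed(s.Aold[0], s.A0[0], s.beta, rho);
  double th = (c0 - u0) * dt / s.dx;
  if (th < 0.0) th = 0.0;
  if (th > 1.0) th = 1.0;
  double W0 = u0 - 4.0 * c0;
  double u1 = s.Qold[1] / s.Aold[1];
  double c1 = wspeed(s.Aold[1], s.A0[1], s.beta, rho);
  double W1 = u1 - 4.0 * c1;
  double uf = (1.0 - th) * u0 + th * u1;
  double Af = (1.0 - th) * s.Aold[0] + th * s.Aold[1];
  double cf = (1.0 - th) * c0 + th * c1;
  double A0 = s.A0[0], dA0 = s.dA0[0];
  double fric = -8.0 * M_PI * mu * uf / (rho * Af);
  double taper = dA0 * ((s.beta / rho) * (std::sqrt(Af) / (A0 * A0)
                                          - 0.5 / (A0 * std::sqrt(A0)))
                        + (2.0 * cf / A0) * (uf - cf));
  return (1.0 - th) * W0 + th * W1 + dt * (fric + taper);
}

// W1 = u + 4c extrapolated to the outlet node (x = L) along dx/dt = u + c
static double extrap_W1(const Segment& s, double dt, double rho, double mu) {
  int n = s.n;
  double u0 = s.Qold[n - 1] / s.Aold[n - 1];
  double c0 = wspeed(s.Aold[n - 1], s.A0[n - 1], s.beta, rho);
  double th = (c0 + u0) * dt / s.dx;
  if (th < 0.0) th = 0.0;
  if (th > 1.0) th = 1.0;
  double W0 = u0 + 4.0 * c0;
  double u1 = s.Qold[n - 2] / s.Aold[n - 2];
  double c1 = wspeed(s.Aold[n - 2], s.A0[n - 2], s.beta, rho);
  double W1 = u1 + 4.0 * c1;
  double uf = (1.0 - th) * u0 + th * u1;
  double Af = (1.0 - th) * s.Aold[n - 1] + th * s.Aold[n - 2];
  double cf = (1.0 - th) * c0 + th * c1;
  double A0 = s.A0[n - 1], dA0 = s.dA0[n - 1];
  double fric = -8.0 * M_PI * mu * uf / (rho * Af);
  double taper = dA0 * ((s.beta / rho) * (std::sqrt(Af) / (A0 * A0)
                                          - 0.5 / (A0 * std::sqrt(A0)))
                        - (2.0 * cf / A0) * (uf + cf));
  return (1.0 - th) * W0 + th * W1 + dt * (fric + taper);
}

// Solve u - 4c(A) = W2 at fixed Q (u = Q/A); Newton on A.
static double solve_inlet_area(double Q, double W2, double A_guess,
                               double A0, double beta, double rho) {
  double A = A_guess;
  for (int it = 0; it < 60; ++it) {
    double c = wspeed(A, A0, beta, rho);
    double g = Q / A - 4.0 * c - W2;
    double dg = -Q / (A * A) - c / A;
    double step = g / dg;
    if (A - step <= 0.0) step = A / 2.0;
    A -= step;
    if (std::fabs(g) < 1e-9) break;
  }
  return A;
}

// ---- main entry ----------------------------------------------------------

// [[Rcpp::export]]
List run_simulation_cpp(List model_in, List inlet_in, List config) {
  Model M;
  List seg_list = model_in["segments"];
  M.rho = as<double>(model_in["rho"]);
  M.mu = as<double>(model_in["mu"]);
  int nseg = seg_list.size();
  M.segs.resize(nseg);
  for (int k = 0; k < nseg; ++k) {
    List sl = seg_list[k];
    Segment& s = M.segs[k];
    s.n = as<int>(sl["n"]);
    s.dx = as<double>(sl["dx"]);
    s.beta = as<double>(sl["beta"]);
    s.gamma = as<double>(sl["gamma"]);
    s.A0 = as<std::vector<double> >(sl["A0"]);
    s.dA0 = as<std::vector<double> >(sl["dA0"]);
    s.A0h = as<std::vector<double> >(sl["A0h"]);
    s.dA0h = as<std::vector<double> >(sl["dA0h"]);
    s.parent = as<int>(sl["parent"]);
    s.A.resize(s.n); s.Q.assign(s.n, 0.0);
    s.Aold.resize(s.n); s.Qold.resize(s.n);
    s.Ah.resize(s.n - 1); s.Qh.resize(s.n - 1); s.F2h.resize(s.n - 1);
  }
  List junc_list = model_in["junctions"];
  M.juncs.resize(junc_list.size());
  for (int k = 0; k < (int)junc_list.size(); ++k) {
    IntegerVector j = junc_list[k];
    M.juncs[k].parent = j[0];
    M.juncs[k].child[0] = j[1];
    M.juncs[k].nchild = 1;
    M.juncs[k].child[1] = -1;
    if (j.size() > 2 && j[2] >= 0) { M.juncs[k].child[1] = j[2]; M.juncs[k].nchild = 2; }
  }
  List term_list = model_in["terminals"];
  M.terms.resize(term_list.size());
  for (int k = 0; k < (int)term_list.size(); ++k) {
    NumericVector t = term_list[k];
    Terminal& tr = M.terms[k];
    tr.seg = (int)t[0]; tr.R1 = t[1]; tr.R2 = t[2]; tr.C = t[3]; tr.pven = t[4];
    tr.vol = 0.0; tr.Q = 0.0;
  }

  // inlet: heart or prescribed flow
  int inlet_mode = as<int>(inlet_in["mode"]); // 0 heart, 1 flow
  Heart H;
  std::vector<double> qin_tab;
  double qin_dt = 0.0;
  double T = as<double>(inlet_in["period"]);
  if (inlet_mode == 0) {
    H.Emax = as<double>(inlet_in["Emax"]); H.Emin = as<double>(inlet_in["Emin"]);
    H.V0 = as<double>(inlet_in["V0"]); H.T = T;
    H.tact = as<double>(inlet_in["tact"]); H.ppre = as<double>(inlet_in["ppre"]);
    H.Rav = as<double>(inlet_in["Rav"]); H.Lav = as<double>(inlet_in["Lav"]);
    H.Rmit = as<double>(inlet_in["Rmit"]);
    H.h_t1 = as<double>(inlet_in["h_t1"]); H.h_n1 = as<double>(inlet_in["h_n1"]);
    H.h_t2 = as<double>(inlet_in["h_t2"]); H.h_n2 = as<double>(inlet_in["h_n2"]);
    // locate the peak of the raw double-Hill shape once
    double best = -1.0, sbest = 0.3;
    for (double s = 0.02; s <= 1.5; s += 1e-4) {
      double v = hill_shape(s, H.h_t1, H.h_n1, H.h_t2, H.h_n2);
      if (v > best) { best = v; sbest = s; }
    }
    H.s_peak = sbest; H.shape_max = best;
    H.V = H.V0 + H.ppre / H.Emin; // diastatic equilibrium start
    H.Qav = 0.0;
  } else {
    qin_tab = as<std::vector<double> >(inlet_in["flow"]);
    qin_dt = as<double>(inlet_in["flow_dt"]);
  }

  double cfl = as<double>(config["cfl"]);
  int max_cycles = as<int>(config["max_cycles"]);
  double tol = as<double>(config["tol"]);
  double p_init = as<double>(config["p_init"]);
  IntegerVector site_seg = config["site_seg"];
  IntegerVector site_node = config["site_node"];
  int nsites = site_seg.size();

  // initial condition: uniform diastolic pressure, zero flow
  double cmax = 0.0, dxmin = 1e30;
  for (int k = 0; k < nseg; ++k) {
    Segment& s = M.segs[k];
    for (int i = 0; i < s.n; ++i) {
      double sq = std::sqrt(s.A0[i]) + p_init * s.A0[i] / s.beta;
      s.A[i] = sq * sq;
      double c = wspeed(s.A[i], s.A0[i], s.beta, M.rho);
      if (c > cmax) cmax = c;
    }
    if (s.dx < dxmin) dxmin = s.dx;
  }
  for (int k = 0; k < (int)M.terms.size(); ++k) M.terms[k].pc = p_init;

  // time step with headroom for systolic stiffening and advection
  double dt = cfl * dxmin / (1.35 * cmax);
  int steps = (int)std::ceil(T / dt);
  dt = T / steps;

  // recording buffers: full resolution over one cycle
  std::vector<std::vector<double> > recP(nsites), recQ(nsites), recA(nsites);
  for (int j = 0; j < nsites; ++j) {
    recP[j].assign(steps, 0.0); recQ[j].assign(steps, 0.0); recA[j].assign(steps, 0.0);
  }
  std::vector<double> rootP(steps, 0.0), rootP_prev(steps, 0.0);
  std::vector<double> recV(steps, 0.0), recQin(steps, 0.0);
  std::vector<double> resid_hist;
  double inlet_vol = 0.0;
  M.junc_resid = 0.0;

  bool converged = false;
  int cycles_run = 0;
  double residual = NA_REAL;
  double cfl_seen = 0.0;

  // scratch for Thomas solve
  std::vector<double> ta, tb, tc_, td;

  for (int cyc = 0; cyc < max_cycles && !converged; ++cyc) {
    inlet_vol = 0.0;
    for (size_t k = 0; k < M.terms.size(); ++k) M.terms[k].vol = 0.0;
    for (int st = 0; st < steps; ++st) {
      double t_new = (st + 1) * dt;
      // swap state into old
      for (int k = 0; k < nseg; ++k) {
        M.segs[k].Aold.swap(M.segs[k].A);
        M.segs[k].Qold.swap(M.segs[k].Q);
      }
      // interior Lax-Wendroff update
      for (int k = 0; k < nseg; ++k) {
        Segment& s = M.segs[k];
        int n = s.n;
        const double rho = M.rho;
        const double fric = -8.0 * M_PI * M.mu / rho;
        // half states
        for (int i = 0; i < n - 1; ++i) {
          double Al = s.Aold[i], Ar = s.Aold[i + 1];
          double Ql = s.Qold[i], Qr = s.Qold[i + 1];
          double sqAl = std::sqrt(Al), sqAr = std::sqrt(Ar);
          double F2l = Ql * Ql / Al + s.beta * Al * sqAl / (3.0 * rho * s.A0[i]);
          double F2r = Qr * Qr / Ar + s.beta * Ar * sqAr / (3.0 * rho * s.A0[i + 1]);
          double Am = 0.5 * (Al + Ar), Qm = 0.5 * (Ql + Qr);
          double A0m = s.A0h[i], dA0m = s.dA0h[i];
          double srcm = fric * Qm / Am +
            (s.beta * dA0m / rho) * ((2.0 / 3.0) * Am * std::sqrt(Am) / (A0m * A0m)
                                     - Am / (2.0 * A0m * std::sqrt(A0m)));
          double Ah = Am - 0.5 * dt / s.dx * (Qr - Ql);
          double Qh = Qm - 0.5 * dt / s.dx * (F2r - F2l) + 0.5 * dt * srcm;
          if (Ah <= 0.0) {
            char buf[128];
            std::snprintf(buf, sizeof(buf),
                          "numerical blow-up (A <= 0) in segment %d at t = %.4f s", k + 1, t_new);
            stop(buf);
          }
          s.Ah[i] = Ah; s.Qh[i] = Qh;
          s.F2h[i] = Qh * Qh / Ah + s.beta * Ah * std::sqrt(Ah) / (3.0 * rho * A0m);
          // CFL monitor on the fly (node i)
          double lam = (std::fabs(Ql / Al) + wspeed(Al, s.A0[i], s.beta, rho)) * dt / s.dx;
          if (lam > cfl_seen) cfl_seen = lam;
        }
        {
          int i = n - 1; // CFL monitor for the last node
          double lam = (std::fabs(s.Qold[i] / s.Aold[i]) +
                        wspeed(s.Aold[i], s.A0[i], s.beta, rho)) * dt / s.dx;
          if (lam > cfl_seen) cfl_seen = lam;
        }
        // full step, interior nodes
        for (int i = 1; i < n - 1; ++i) {
          double Amid = 0.5 * (s.Ah[i - 1] + s.Ah[i]);
          double Qmid = 0.5 * (s.Qh[i - 1] + s.Qh[i]);
          double src = fric * Qmid / Amid +
            (s.beta * s.dA0[i] / rho) * ((2.0 / 3.0) * Amid * std::sqrt(Amid) / (s.A0[i] * s.A0[i])
                                         - Amid / (2.0 * s.A0[i] * std::sqrt(s.A0[i])));
          double An = s.Aold[i] - dt / s.dx * (s.Qh[i] - s.Qh[i - 1]);
          double Qn = s.Qold[i] - dt / s.dx * (s.F2h[i] - s.F2h[i - 1]) + dt * src;
          if (An <= 0.0) {
            char buf[128];
            std::snprintf(buf, sizeof(buf),
                          "numerical blow-up (A <= 0) in segment %d at t = %.4f s", k + 1, t_new);
            stop(buf);
          }
          double p = p_el(An, s.A0[i], s.beta);
          if (std::fabs(p) > 400.0 * MMHG) {
            char buf[160];
            std::snprintf(buf, sizeof(buf),
                          "numerical blow-up (|p| > 400 mmHg) in segment %d at t = %.4f s", k + 1, t_new);
            stop(buf);
          }
          s.A[i] = An; s.Q[i] = Qn;
        }
      }
      if (cfl_seen > 1.0) {
        char buf[160];
        std::snprintf(buf, sizeof(buf),
                      "CFL condition violated (max characteristic Courant number %.3f > 1); reduce the time step or spatial resolution", cfl_seen);
        stop(buf);
      }

      // ---- inlet boundary (root segment, node 0) ----
      {
        Segment& s = M.segs[0];
        double W2 = extrap_W2(s, dt, M.rho, M.mu);
        double Qin;
        if (inlet_mode == 1) {
          double tq = (st + 1) * dt; // prescribed-flow runs are single-pass
          int idx = (int)(tq / qin_dt);
          double Qtab;
          if (idx >= (int)qin_tab.size() - 1) Qtab = qin_tab.back();
          else {
            double w = tq / qin_dt - idx;
            Qtab = (1.0 - w) * qin_tab[idx] + w * qin_tab[idx + 1];
          }
          Qin = Qtab;
          s.A[0] = solve_inlet_area(Qin, W2, s.Aold[0], s.A0[0], s.beta, M.rho);
          s.Q[0] = Qin;
        } else {
          double tc = t_new - std::floor(t_new / H.T) * H.T;
          double sh = hill_shape(tc * H.s_peak / H.tact,
                                 H.h_t1, H.h_n1, H.h_t2, H.h_n2) / H.shape_max;
          double E = H.Emin + (H.Emax - H.Emin) * sh;
          double plv = E * (H.V - H.V0);
          double p_root_old = p_el(s.Aold[0], s.A0[0], s.beta);
          double Qav = 0.0, A = s.Aold[0];
          if (H.Lav > 0.0) {
            double q = H.Qav + dt * (plv - p_root_old - H.Rav * H.Qav) / H.Lav;
            if (q < 0.0 || (plv <= p_root_old && H.Qav <= 0.0)) q = 0.0;
            Qav = q;
            A = solve_inlet_area(Qav, W2, s.Aold[0], s.A0[0], s.beta, M.rho);
          } else if (plv > p_root_old) {
            // valve open: solve the valve law and the characteristic jointly
            for (int it = 0; it < 60; ++it) {
              double c = wspeed(A, s.A0[0], s.beta, M.rho);
              double p = p_el(A, s.A0[0], s.beta);
              double Q = (plv - p) / H.Rav;
              double g = Q / A - 4.0 * c - W2;
              double dQdA = -(M.rho * c * c / A) / H.Rav;
              double dg = (dQdA * A - Q) / (A * A) - c / A;
              double stp = g / dg;
              if (A - stp <= 0.0) stp = A / 2.0;
              A -= stp;
              if (std::fabs(g) < 1e-9) break;
            }
            Qav = (plv - p_el(A, s.A0[0], s.beta)) / H.Rav;
            if (Qav < 0.0) { Qav = 0.0; A = solve_inlet_area(0.0, W2, s.Aold[0], s.A0[0], s.beta, M.rho); }
          } else {
            A = solve_inlet_area(0.0, W2, s.Aold[0], s.A0[0], s.beta, M.rho);
          }
          double Qmit = (H.ppre > plv) ? (H.ppre - plv) / H.Rmit : 0.0;
          H.V += dt * (Qmit - Qav);
          H.Qav = Qav;
          s.A[0] = A; s.Q[0] = Qav;
          Qin = Qav;
          recV[st] = H.V;
        }
        recQin[st] = Qin;
        inlet_vol += Qin * dt;
      }

      // ---- junctions ----
      for (size_t jk = 0; jk < M.juncs.size(); ++jk) {
        Junction& J = M.juncs[jk];
        Segment& sp = M.segs[J.parent];
        int np = sp.n;
        double A0p = sp.A0[np - 1], bp = sp.beta;
        double W1 = extrap_W1(sp, dt, M.rho, M.mu);
        int nc = J.nchild;
        double W2c[2], A0c[2], bc[2];
        for (int c = 0; c < nc; ++c) {
          Segment& sc = M.segs[J.child[c]];
          W2c[c] = extrap_W2(sc, dt, M.rho, M.mu);
          A0c[c] = sc.A0[0]; bc[c] = sc.beta;
        }
        // unknowns x = (A_p, A_c1[, A_c2])
        double x[3];
        x[0] = sp.Aold[np - 1];
        for (int c = 0; c < nc; ++c) x[1 + c] = M.segs[J.child[c]].Aold[0];
        int dim = 1 + nc;
        double R[3], Jm[3][3];
        bool ok = false;
        for (int it = 0; it < 80; ++it) {
          double cp = wspeed(x[0], A0p, bp, M.rho);
          double up = W1 - 4.0 * cp;
          double pp = p_el(x[0], A0p, bp);
          double uc[2], cc[2], pc2[2];
          for (int c = 0; c < nc; ++c) {
            cc[c] = wspeed(x[1 + c], A0c[c], bc[c], M.rho);
            uc[c] = W2c[c] + 4.0 * cc[c];
            pc2[c] = p_el(x[1 + c], A0c[c], bc[c]);
          }
          R[0] = x[0] * up;
          for (int c = 0; c < nc; ++c) R[0] -= x[1 + c] * uc[c];
          for (int c = 0; c < nc; ++c) {
            R[1 + c] = pp + 0.5 * M.rho * up * up - pc2[c] - 0.5 * M.rho * uc[c] * uc[c];
          }
          double qscale = std::fabs(x[0] * up) + 1.0;
          double pscale = std::fabs(pp) + 1e3;
          bool done = std::fabs(R[0]) < 1e-9 * qscale;
          for (int c = 0; c < nc; ++c) done = done && std::fabs(R[1 + c]) < 1e-9 * pscale;
          if (done) { ok = true; break; }
          // Jacobian
          for (int a = 0; a < dim; ++a) for (int b = 0; b < dim; ++b) Jm[a][b] = 0.0;
          Jm[0][0] = up - cp;                       // d(A u_p)/dA_p, du_p/dA = -c/A
          for (int c = 0; c < nc; ++c) Jm[0][1 + c] = -(uc[c] + cc[c]);
          for (int c = 0; c < nc; ++c) {
            Jm[1 + c][0] = M.rho * cp * (cp - up) / x[0];
            Jm[1 + c][1 + c] = -M.rho * cc[c] * (cc[c] + uc[c]) / x[1 + c];
          }
          // solve Jm * d = R (Gaussian elimination, dim <= 3)
          double Aug[3][4];
          for (int a = 0; a < dim; ++a) {
            for (int b = 0; b < dim; ++b) Aug[a][b] = Jm[a][b];
            Aug[a][dim] = R[a];
          }
          for (int col = 0; col < dim; ++col) {
            int piv = col;
            for (int r2 = col + 1; r2 < dim; ++r2)
              if (std::fabs(Aug[r2][col]) > std::fabs(Aug[piv][col])) piv = r2;
            if (piv != col) for (int b = 0; b <= dim; ++b) std::swap(Aug[col][b], Aug[piv][b]);
            for (int r2 = col + 1; r2 < dim; ++r2) {
              double f = Aug[r2][col] / Aug[col][col];
              for (int b = col; b <= dim; ++b) Aug[r2][b] -= f * Aug[col][b];
            }
          }
          double d[3];
          for (int a = dim - 1; a >= 0; --a) {
            double ssum = Aug[a][dim];
            for (int b = a + 1; b < dim; ++b) ssum -= Aug[a][b] * d[b];
            d[a] = ssum / Aug[a][a];
          }
          for (int a = 0; a < dim; ++a) {
            double stp = d[a];
            if (x[a] - stp <= 0.0) stp = x[a] / 2.0;
            x[a] -= stp;
          }
        }
        if (!ok) {
          char buf[128];
          std::snprintf(buf, sizeof(buf),
                        "junction Newton iteration failed at parent segment %d, t = %.4f s", J.parent + 1, t_new);
          stop(buf);
        }
        // write back and track the mass defect
        double cp = wspeed(x[0], A0p, bp, M.rho);
        double up = W1 - 4.0 * cp;
        sp.A[np - 1] = x[0]; sp.Q[np - 1] = x[0] * up;
        double qsum = 0.0;
        for (int c = 0; c < nc; ++c) {
          Segment& sc = M.segs[J.child[c]];
          double ccv = wspeed(x[1 + c], A0c[c], bc[c], M.rho);
          double ucv = W2c[c] + 4.0 * ccv;
          sc.A[0] = x[1 + c]; sc.Q[0] = x[1 + c] * ucv;
          qsum += sc.Q[0];
        }
        double rel = std::fabs(sp.Q[np - 1] - qsum) /
          std::max(1.0, std::fabs(sp.Q[np - 1]));
        if (rel > M.junc_resid) M.junc_resid = rel;
      }

      // ---- Windkessel terminals ----
      for (size_t tk = 0; tk < M.terms.size(); ++tk) {
        Terminal& tr = M.terms[tk];
        Segment& s = M.segs[tr.seg];
        int n = s.n;
        double W1 = extrap_W1(s, dt, M.rho, M.mu);
        double A = s.Aold[n - 1];
        double A0 = s.A0[n - 1];
        for (int it = 0; it < 60; ++it) {
          double c = wspeed(A, A0, s.beta, M.rho);
          double p = p_el(A, A0, s.beta);
          double Q = (p - tr.pc) / tr.R1;
          double g = Q / A + 4.0 * c - W1;
          double dQdA = (M.rho * c * c / A) / tr.R1;
          double dg = (dQdA * A - Q) / (A * A) + c / A;
          double stp = g / dg;
          if (A - stp <= 0.0) stp = A / 2.0;
          A -= stp;
          if (std::fabs(g) < 1e-9) break;
        }
        double p = p_el(A, A0, s.beta);
        double Q = (p - tr.pc) / tr.R1;
        s.A[n - 1] = A; s.Q[n - 1] = Q;
        tr.pc += dt * (Q - (tr.pc - tr.pven) / tr.R2) / tr.C;
        tr.Q = Q;
        tr.vol += Q * dt;
      }

      // ---- implicit Kelvin-Voigt diffusion on Q (Thomas per segment) ----
      for (int k = 0; k < nseg; ++k) {
        Segment& s = M.segs[k];
        if (s.gamma <= 0.0) continue;
        int n = s.n;
        ta.assign(n, 0.0); tb.assign(n, 1.0); tc_.assign(n, 0.0);
        td.assign(n, 0.0);
        td[0] = s.Q[0]; td[n - 1] = s.Q[n - 1];
        double inv_dx2 = 1.0 / (s.dx * s.dx);
        for (int i = 1; i < n - 1; ++i) {
          double gmR = s.gamma / (s.A0h[i] * std::sqrt(0.5 * (s.A[i] + s.A[i + 1])));
          double gmL = s.gamma / (s.A0h[i - 1] * std::sqrt(0.5 * (s.A[i - 1] + s.A[i])));
          double fac = dt * (s.A[i] / M.rho) * inv_dx2;
          ta[i] = -fac * gmL;
          tc_[i] = -fac * gmR;
          tb[i] = 1.0 + fac * (gmL + gmR);
          td[i] = s.Q[i];
        }
        for (int i = 1; i < n; ++i) {
          double m = ta[i] / tb[i - 1];
          tb[i] -= m * tc_[i - 1];
          td[i] -= m * td[i - 1];
        }
        s.Q[n - 1] = td[n - 1] / tb[n - 1];
        for (int i = n - 2; i >= 0; --i) s.Q[i] = (td[i] - tc_[i] * s.Q[i + 1]) / tb[i];
      }

      // ---- record ----
      for (int j = 0; j < nsites; ++j) {
        Segment& s = M.segs[site_seg[j]];
        int i = site_node[j];
        // recorded pressure includes the Kelvin-Voigt viscous stress,
        // dA/dt = -dQ/dx from the mass equation
        double dQdx;
        if (i == 0) dQdx = (s.Q[1] - s.Q[0]) / s.dx;
        else if (i == s.n - 1) dQdx = (s.Q[i] - s.Q[i - 1]) / s.dx;
        else dQdx = (s.Q[i + 1] - s.Q[i - 1]) / (2.0 * s.dx);
        double pvisc = s.gamma / (s.A0[i] * std::sqrt(s.A[i])) * (-dQdx);
        recP[j][st] = p_el(s.A[i], s.A0[i], s.beta) + pvisc;
        recQ[j][st] = s.Q[i];
        recA[j][st] = s.A[i];
      }
      {
        Segment& s = M.segs[0];
        rootP[st] = p_el(s.A[0], s.A0[0], s.beta);
      }
    } // step loop

    cycles_run = cyc + 1;
    if (cyc > 0) {
      double r = 0.0;
      for (int st = 0; st < steps; ++st) {
        double d = std::fabs(rootP[st] - rootP_prev[st]);
        if (d > r) r = d;
      }
      residual = r;
      resid_hist.push_back(r / MMHG);
      if (r <= tol) converged = true;
    }
    rootP_prev = rootP;
  } // cycle loop

  // package results
  NumericMatrix P(steps, nsites), Q(steps, nsites), Aout(steps, nsites);
  for (int j = 0; j < nsites; ++j) {
    for (int st = 0; st < steps; ++st) {
      P(st, j) = recP[j][st] / MMHG;
      Q(st, j) = recQ[j][st];
      Aout(st, j) = recA[j][st];
    }
  }
  NumericVector tvec(steps);
  for (int st = 0; st < steps; ++st) tvec[st] = (st + 1) * dt;
  NumericVector tv(M.terms.size());
  for (size_t k = 0; k < M.terms.size(); ++k) tv[k] = M.terms[k].vol;
  double edv = NA_REAL, esv = NA_REAL;
  if (inlet_mode == 0) {
    edv = *std::max_element(recV.begin(), recV.end());
    esv = *std::min_element(recV.begin(), recV.end());
  }
  NumericVector rootP_out(steps);
  for (int st = 0; st < steps; ++st) rootP_out[st] = rootP[st] / MMHG;

  return List::create(
    _["converged"] = converged,
    _["cycles"] = cycles_run,
    _["residual"] = residual / MMHG,
    _["residual_history"] = wrap(resid_hist),
    _["dt"] = dt,
    _["time"] = tvec,
    _["pressure"] = P,
    _["flow"] = Q,
    _["area"] = Aout,
    _["root_pressure"] = rootP_out,
    _["volume_trace"] = wrap(recV),
    _["inflow_trace"] = wrap(recQin),
    _["edv"] = edv,
    _["esv"] = esv,
    _["inlet_volume"] = inlet_vol,
    _["terminal_volumes"] = tv,
    _["junction_residual"] = M.junc_resid,
    _["courant_max"] = cfl_seen
  );
}
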
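// 1-D pulse-wave network solver.
//
// Governing equations per segment (SI units):
//   dA/dt + dQ/dx = 0
//   dQ/dt + d(Q^2/A)/dx + (A/rho) dP/dx = -f_c * Q/A,   f_c = k_f * pi * mu / rho
// with a tube law P(A) tied to the local reference area Aref(x) and
// distensibility D (Pa^-1).  Explicit MacCormack predictor-corrector in the
// interior; characteristic (Riemann-invariant) boundary treatment at the
// inlet, junctions (static-pressure continuity + mass conservation, Newton)
// and three-element Windkessel terminals (implicit capacitor update).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct WallLaw {
  double D;     // Pa^-1 at reference
  double b;     // nonlinearity (0 = linear area-pressure law)
  double Pref;  // Pa
};

// pressure from area
inline double wall_p(const WallLaw &w, double A, double Aref) {
  double a = A / Aref;
  if (w.b == 0.0) return w.Pref + (a - 1.0) / w.D;
  return w.Pref + (std::exp(w.b * (a - 1.0)) - 1.0) / (w.D * w.b);
}

// dP/dA
inline double wall_dpdA(const WallLaw &w, double A, double Aref) {
  double a = A / Aref;
  if (w.b == 0.0) return 1.0 / (w.D * Aref);
  return std::exp(w.b * (a - 1.0)) / (w.D * Aref);
}

// area from pressure (inverse law)
inline double wall_A(const WallLaw &w, double P, double Aref) {
  if (w.b == 0.0) return Aref * (1.0 + w.D * (P - w.Pref));
  double z = 1.0 + w.D * w.b * (P - w.Pref);
  if (z <= 0.0) return -1.0;
  return Aref * (1.0 + std::log(z) / w.b);
}

struct Seg {
  int n;
  double dx;
  std::vector<double> Aref;
  WallLaw law;
  int parent;                 // -1 for root
  std::vector<int> children;  // segment indices
  int term;                   // terminal index or -1
  std::vector<double> A, Q, Ap, Qp, An, Qn;
};

struct Term {
  double R1, R2, C, Pout;  // SI
  double Pc;               // capacitor pressure state
};

struct NetError : public std::exception {
  std::string msg;
  explicit NetError(std::string m) : msg(std::move(m)) {}
  const char *what() const noexcept override { return msg.c_str(); }
};

inline double wave_c(const Seg &s, double A, int node, double rho) {
  double c2 = A * wall_dpdA(s.law, A, s.Aref[node]) / rho;
  if (c2 <= 0.0) throw NetError("non-positive wave speed (area collapse)");
  return std::sqrt(c2);
}

// Along a characteristic u = W -/+ 2c(A) with the linear tube law
// (c ~ sqrt(A), dc/dA = c/(2A)):  d(A*u)/dA = W -/+ 3c.  The same form is
// used as a local approximation for the stiffening law.

}  // namespace

// [[Rcpp::export]]
List solve_network_cpp(IntegerVector seg_n, NumericVector seg_dx,
                       List seg_Aref, NumericVector seg_D, NumericVector seg_b,
                       NumericVector seg_Pref, IntegerVector parent,
                       IntegerVector term_of_seg, NumericVector term_R1,
                       NumericVector term_R2, NumericVector term_C,
                       NumericVector term_Pout, NumericVector inflow,
                       double dt, int max_cycles, double tol, double rho,
                       double fric_coef, IntegerVector site_seg,
                       IntegerVector site_node, double P_init) {
  const int ns = seg_n.size();
  const int nstep = inflow.size();
  const int nsite = site_seg.size();

  std::vector<Seg> S(ns);
  int root = -1;
  for (int i = 0; i < ns; ++i) {
    Seg &s = S[i];
    s.n = seg_n[i];
    s.dx = seg_dx[i];
    NumericVector ar = seg_Aref[i];
    s.Aref.assign(ar.begin(), ar.end());
    s.law.D = seg_D[i];
    s.law.b = seg_b[i];
    s.law.Pref = seg_Pref[i];
    s.parent = parent[i];
    s.term = term_of_seg[i];
    if (s.parent < 0) root = i;
    s.A.resize(s.n);
    s.Q.assign(s.n, 0.0);
    s.Ap.resize(s.n);
    s.Qp.resize(s.n);
    s.An.resize(s.n);
    s.Qn.resize(s.n);
    for (int k = 0; k < s.n; ++k) {
      double A0 = wall_A(s.law, P_init, s.Aref[k]);
      if (A0 <= 0.0) throw NetError("initial pressure collapses segment area");
      s.A[k] = A0;
    }
  }
  if (root < 0) stop("no root segment");
  for (int i = 0; i < ns; ++i)
    if (S[i].parent >= 0) S[S[i].parent].children.push_back(i);

  const int nterm = term_R1.size();
  std::vector<Term> T(nterm);
  for (int j = 0; j < nterm; ++j) {
    T[j].R1 = term_R1[j];
    T[j].R2 = term_R2[j];
    T[j].C = term_C[j];
    T[j].Pout = term_Pout[j];
    T[j].Pc = P_init;
  }

  // recording buffers: current and previous cycle
  NumericMatrix curP(nstep, nsite), curQ(nstep, nsite);
  NumericMatrix prevP(nstep, nsite), prevQ(nstep, nsite);
  NumericMatrix termQ(nstep, nterm);
  NumericVector rootP(nstep), rootP_prev(nstep);

  bool converged = false;
  int cycles = 0;
  double junc_imbal = 0.0;   // max |Qp - sum Qc| over final cycle (m^3/s)
  double root_vol = 0.0;     // inflow volume over final cycle
  std::vector<double> term_vol(nterm, 0.0);
  double storage0 = 0.0, storage1 = 0.0;  // tube+capacitor stored volume

  auto stored_volume = [&]() {
    double v = 0.0;
    for (int i = 0; i < ns; ++i) {
      const Seg &s = S[i];
      for (int k = 0; k < s.n - 1; ++k)
        v += 0.5 * (s.A[k] + s.A[k + 1]) * s.dx;
    }
    for (int j = 0; j < nterm; ++j) v += T[j].C * T[j].Pc;
    return v;
  };

  const int NEWT = 60;
  const double ATOL = 1e-13;

  for (int cyc = 0; cyc < max_cycles; ++cyc) {
    // roll buffers
    std::copy(curP.begin(), curP.end(), prevP.begin());
    std::copy(curQ.begin(), curQ.end(), prevQ.begin());
    std::copy(rootP.begin(), rootP.end(), rootP_prev.begin());
    junc_imbal = 0.0;
    root_vol = 0.0;
    std::fill(term_vol.begin(), term_vol.end(), 0.0);
    storage0 = stored_volume();

    for (int it = 0; it < nstep; ++it) {
      double Qin = inflow[it];

      // --- boundary Riemann invariants from the time-n state ---
      // Traced back along the characteristics with the taper and friction
      // source terms: dW+/dt = -k u/A - u c G, dW-/dt = -k u/A + u c G,
      // G = Aref'/Aref. (W+- = u +- 2c is exact for the linear tube law.)
      std::vector<double> Wout(ns), Win(ns);
      for (int i = 0; i < ns; ++i) {
        Seg &s = S[i];
        const int n = s.n;
        {  // outlet, forward characteristic
          double c1 = wave_c(s, s.A[n - 1], n - 1, rho);
          double u1 = s.Q[n - 1] / s.A[n - 1];
          double lam = (u1 + c1) * dt / s.dx;
          if (lam < 0.0) lam = 0.0;
          if (lam > 1.0) lam = 1.0;
          double Af = s.A[n - 1] - lam * (s.A[n - 1] - s.A[n - 2]);
          double Qf = s.Q[n - 1] - lam * (s.Q[n - 1] - s.Q[n - 2]);
          double Arf = s.Aref[n - 1] - lam * (s.Aref[n - 1] - s.Aref[n - 2]);
          double cf = std::sqrt(Af * wall_dpdA(s.law, Af, Arf) / rho);
          double uf = Qf / Af;
          double Gf = (s.Aref[n - 1] - s.Aref[n - 2]) / (s.dx * Arf);
          Wout[i] = uf + 2.0 * cf +
                    dt * (-fric_coef * uf / Af - uf * cf * Gf);
        }
        {  // inlet, backward characteristic
          double c0 = wave_c(s, s.A[0], 0, rho);
          double u0 = s.Q[0] / s.A[0];
          double mu2 = (c0 - u0) * dt / s.dx;
          if (mu2 < 0.0) mu2 = 0.0;
          if (mu2 > 1.0) mu2 = 1.0;
          double Af = s.A[0] + mu2 * (s.A[1] - s.A[0]);
          double Qf = s.Q[0] + mu2 * (s.Q[1] - s.Q[0]);
          double Arf = s.Aref[0] + mu2 * (s.Aref[1] - s.Aref[0]);
          double cf = std::sqrt(Af * wall_dpdA(s.law, Af, Arf) / rho);
          double uf = Qf / Af;
          double Gf = (s.Aref[1] - s.Aref[0]) / (s.dx * Arf);
          Win[i] = uf - 2.0 * cf +
                   dt * (-fric_coef * uf / Af + uf * cf * Gf);
        }
      }

      // --- interior MacCormack ---
      for (int i = 0; i < ns; ++i) {
        Seg &s = S[i];
        const int n = s.n;
        const double r = dt / s.dx;
        std::vector<double> p(n), pp(n);
        for (int k = 0; k < n; ++k) p[k] = wall_p(s.law, s.A[k], s.Aref[k]);
        // predictor (forward differences), valid 0..n-2
        for (int k = 0; k < n - 1; ++k) {
          double F2k = s.Q[k] * s.Q[k] / s.A[k];
          double F2k1 = s.Q[k + 1] * s.Q[k + 1] / s.A[k + 1];
          s.Ap[k] = s.A[k] - r * (s.Q[k + 1] - s.Q[k]);
          s.Qp[k] = s.Q[k] - r * (F2k1 - F2k) -
                    r * (s.A[k] / rho) * (p[k + 1] - p[k]) -
                    dt * fric_coef * s.Q[k] / s.A[k];
          if (s.Ap[k] <= 0.0 || !std::isfinite(s.Qp[k]))
            throw NetError("solver blow-up (predictor), segment " +
                           std::to_string(i + 1) + ", step " +
                           std::to_string(it + 1));
        }
        s.Ap[n - 1] = s.A[n - 1];
        s.Qp[n - 1] = s.Q[n - 1];
        for (int k = 0; k < n; ++k) pp[k] = wall_p(s.law, s.Ap[k], s.Aref[k]);
        // corrector (backward differences), interior 1..n-2
        for (int k = 1; k < n - 1; ++k) {
          double F2k = s.Qp[k] * s.Qp[k] / s.Ap[k];
          double F2km = s.Qp[k - 1] * s.Qp[k - 1] / s.Ap[k - 1];
          s.An[k] = 0.5 * (s.A[k] + s.Ap[k] - r * (s.Qp[k] - s.Qp[k - 1]));
          s.Qn[k] = 0.5 * (s.Q[k] + s.Qp[k] - r * (F2k - F2km) -
                           r * (s.Ap[k] / rho) * (pp[k] - pp[k - 1]) -
                           dt * fric_coef * s.Qp[k] / s.Ap[k]);
          if (s.An[k] <= 0.0 || !std::isfinite(s.Qn[k]))
            throw NetError("solver blow-up (corrector), segment " +
                           std::to_string(i + 1) + ", step " +
                           std::to_string(it + 1));
        }
        s.An[0] = s.A[0];
        s.Qn[0] = s.Q[0];
        s.An[n - 1] = s.A[n - 1];
        s.Qn[n - 1] = s.Q[n - 1];
      }

      // --- root inlet: prescribed Q, backward characteristic from interior
      {
        Seg &s = S[root];
        double Wm = Win[root];
        double A = s.A[0];
        for (int k = 0; k < NEWT; ++k) {
          double c = wave_c(s, A, 0, rho);
          double g = Qin / A - 2.0 * c - Wm;
          double dg = -Qin / (A * A) - c / A;  // linear-law dc/dA = c/(2A)
          double dA = -g / dg;
          A += dA;
          if (A <= 0.0) A = 0.5 * (A - dA);
          if (std::fabs(dA) < ATOL + 1e-12 * A) break;
        }
        s.An[0] = A;
        s.Qn[0] = Qin;
      }

      // --- junctions: parent outlet + children inlets ---
      for (int i = 0; i < ns; ++i) {
        Seg &sp = S[i];
        const int m = (int)sp.children.size();
        if (m == 0) continue;
        const int np = sp.n;
        double Wp = Wout[i];
        std::vector<double> Wm(m);
        std::vector<double> x(m + 1);
        x[0] = sp.A[np - 1];
        for (int j = 0; j < m; ++j) {
          Wm[j] = Win[sp.children[j]];
          x[j + 1] = S[sp.children[j]].A[0];
        }
        // Newton on (A_parent, A_child_1..m)
        for (int k = 0; k < NEWT; ++k) {
          std::vector<double> res(m + 1, 0.0);
          std::vector<std::vector<double>> J(m + 1,
                                             std::vector<double>(m + 1, 0.0));
          double cp = wave_c(sp, x[0], np - 1, rho);
          double up = Wp - 2.0 * cp;
          double pP = wall_p(sp.law, x[0], sp.Aref[np - 1]);
          double dpP = wall_dpdA(sp.law, x[0], sp.Aref[np - 1]);
          res[0] = x[0] * up;
          J[0][0] = Wp - 3.0 * cp;  // d(A u)/dA on the forward characteristic
          for (int j = 0; j < m; ++j) {
            Seg &sc = S[sp.children[j]];
            double cc = wave_c(sc, x[j + 1], 0, rho);
            double uc = Wm[j] + 2.0 * cc;
            res[0] -= x[j + 1] * uc;
            J[0][j + 1] = -(Wm[j] + 3.0 * cc);
            res[j + 1] = pP - wall_p(sc.law, x[j + 1], sc.Aref[0]);
            J[j + 1][0] = dpP;
            J[j + 1][j + 1] = -wall_dpdA(sc.law, x[j + 1], sc.Aref[0]);
          }
          // gaussian elimination with partial pivoting
          int dim = m + 1;
          std::vector<double> rhs(dim);
          for (int a = 0; a < dim; ++a) rhs[a] = -res[a];
          for (int col = 0; col < dim; ++col) {
            int piv = col;
            for (int rr = col + 1; rr < dim; ++rr)
              if (std::fabs(J[rr][col]) > std::fabs(J[piv][col])) piv = rr;
            std::swap(J[col], J[piv]);
            std::swap(rhs[col], rhs[piv]);
            double d = J[col][col];
            if (d == 0.0) throw NetError("singular junction Jacobian");
            for (int rr = col + 1; rr < dim; ++rr) {
              double f = J[rr][col] / d;
              for (int cc2 = col; cc2 < dim; ++cc2) J[rr][cc2] -= f * J[col][cc2];
              rhs[rr] -= f * rhs[col];
            }
          }
          std::vector<double> dx2(dim);
          for (int rr = dim - 1; rr >= 0; --rr) {
            double acc = rhs[rr];
            for (int cc2 = rr + 1; cc2 < dim; ++cc2) acc -= J[rr][cc2] * dx2[cc2];
            dx2[rr] = acc / J[rr][rr];
          }
          double maxrel = 0.0;
          for (int a = 0; a < dim; ++a) {
            double Anew = x[a] + dx2[a];
            if (Anew <= 0.0) Anew = 0.5 * x[a];
            maxrel = std::max(maxrel, std::fabs(Anew - x[a]) / x[a]);
            x[a] = Anew;
          }
          if (maxrel < 1e-13) break;
        }
        double cp = wave_c(sp, x[0], np - 1, rho);
        double up = Wp - 2.0 * cp;
        sp.An[np - 1] = x[0];
        sp.Qn[np - 1] = x[0] * up;
        double qsum = 0.0;
        for (int j = 0; j < m; ++j) {
          Seg &sc = S[sp.children[j]];
          double cc = wave_c(sc, x[j + 1], 0, rho);
          double uc = Wm[j] + 2.0 * cc;
          sc.An[0] = x[j + 1];
          sc.Qn[0] = x[j + 1] * uc;
          qsum += sc.Qn[0];
        }
        junc_imbal = std::max(junc_imbal, std::fabs(sp.Qn[np - 1] - qsum));
      }

      // --- terminals: 3-element Windkessel, implicit capacitor ---
      for (int i = 0; i < ns; ++i) {
        Seg &s = S[i];
        if (s.term < 0) continue;
        Term &t = T[s.term];
        const int n = s.n;
        double Wp = Wout[i];
        double alpha = 1.0 + dt / (t.R2 * t.C);
        double A = s.A[n - 1];
        for (int k = 0; k < NEWT; ++k) {
          double c = wave_c(s, A, n - 1, rho);
          double u = Wp - 2.0 * c;
          double Q = A * u;
          double Pcn = (t.Pc + dt / t.C * (Q + t.Pout / t.R2)) / alpha;
          double f = wall_p(s.law, A, s.Aref[n - 1]) - Pcn - Q * t.R1;
          double dQ = Wp - 3.0 * c;
          double df = wall_dpdA(s.law, A, s.Aref[n - 1]) -
                      dQ * (dt / (t.C * alpha) + t.R1);
          double dA = -f / df;
          A += dA;
          if (A <= 0.0) A = 0.5 * (A - dA);
          if (std::fabs(dA) < ATOL + 1e-12 * A) break;
        }
        double c = wave_c(s, A, n - 1, rho);
        double u = Wp - 2.0 * c;
        double Q = A * u;
        t.Pc = (t.Pc + dt / t.C * (Q + t.Pout / t.R2)) / alpha;
        s.An[n - 1] = A;
        s.Qn[n - 1] = Q;
        termQ(it, s.term) = Q;
        term_vol[s.term] += Q * dt;
      }

      // commit
      for (int i = 0; i < ns; ++i) {
        Seg &s = S[i];
        s.A.swap(s.An);
        s.Q.swap(s.Qn);
      }
      root_vol += Qin * dt;

      // record
      for (int sidx = 0; sidx < nsite; ++sidx) {
        const Seg &s = S[site_seg[sidx]];
        int k = site_node[sidx];
        curP(it, sidx) = wall_p(s.law, s.A[k], s.Aref[k]);
        curQ(it, sidx) = s.Q[k];
      }
      rootP[it] = wall_p(S[root].law, S[root].A[0], S[root].Aref[0]);
    }

    storage1 = stored_volume();
    cycles = cyc + 1;
    if (cyc >= 1) {
      double dmax = 0.0, pmax = 0.0;
      for (int it = 0; it < nstep; ++it) {
        dmax = std::max(dmax, std::fabs(rootP[it] - rootP_prev[it]));
        pmax = std::max(pmax, std::fabs(rootP[it]));
      }
      if (pmax > 0.0 && dmax / pmax < tol) {
        converged = true;
        break;
      }
    }
  }

  std::vector<double> pc_final(nterm);
  for (int j = 0; j < nterm; ++j) pc_final[j] = T[j].Pc;

  return List::create(
      _["converged"] = converged, _["cycles_used"] = cycles,
      _["site_P"] = curP, _["site_Q"] = curQ, _["term_Q"] = termQ,
      _["root_P"] = rootP, _["root_volume"] = root_vol,
      _["term_volumes"] = NumericVector(term_vol.begin(), term_vol.end()),
      _["storage_change"] = storage1 - storage0,
      _["junction_imbalance"] = junc_imbal,
      _["term_Pc"] = NumericVector(pc_final.begin(), pc_final.end()),
      _["dt"] = dt);
}
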
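// Voxel-native staggered-grid (MAC) finite-volume solver for steady laminar
// incompressible flow with passive-scalar heat transfer, plus 3-D
// connected-component labelling and wall-face field extraction.
//
// Cell flags: 0 = solid (no-slip wall), 1 = fluid, 2 = slip wall (symmetry).
// Flow axis is y (axis 1): inlet faces at j = 0, outlet faces at j = ny.
// Face codes: 0 = fixed zero (wall), 1 = active unknown, 2 = inlet (unknown,
// total-pressure condition), 3 = outlet (prescribed uniform velocity).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

namespace {

struct Grid {
  int nc[3];        // cell counts
  long sc[3];       // cell strides
  int nf[3][3];     // face-grid dims for each axis a
  long sf[3][3];    // face-grid strides
  long ncell;
  long nface[3];
};

Grid make_grid(const IntegerVector& dim) {
  Grid g;
  for (int a = 0; a < 3; ++a) g.nc[a] = dim[a];
  g.sc[0] = 1; g.sc[1] = g.nc[0]; g.sc[2] = (long)g.nc[0] * g.nc[1];
  g.ncell = (long)g.nc[0] * g.nc[1] * g.nc[2];
  for (int a = 0; a < 3; ++a) {
    for (int m = 0; m < 3; ++m) g.nf[a][m] = g.nc[m] + (m == a ? 1 : 0);
    g.sf[a][0] = 1;
    g.sf[a][1] = g.nf[a][0];
    g.sf[a][2] = (long)g.nf[a][0] * g.nf[a][1];
    g.nface[a] = (long)g.nf[a][0] * g.nf[a][1] * g.nf[a][2];
  }
  return g;
}

inline long cidx(const Grid& g, int i, int j, int k) {
  return i + g.sc[1] * j + g.sc[2] * k;
}
inline long fidx(const Grid& g, int a, int i, int j, int k) {
  return i + g.sf[a][1] * j + g.sf[a][2] * k;
}
// cell flag with out-of-grid treated as solid
inline int cflag(const Grid& g, const int* flag, int i, int j, int k) {
  if (i < 0 || j < 0 || k < 0 || i >= g.nc[0] || j >= g.nc[1] || k >= g.nc[2])
    return 0;
  return flag[cidx(g, i, j, k)];
}

} // namespace

// ---------------------------------------------------------------------------
// 6-connectivity connected components
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cc_label6")]]
IntegerVector cc_label6(LogicalVector mask, IntegerVector dim) {
  Grid g = make_grid(dim);
  IntegerVector lab(g.ncell, 0);
  std::vector<long> stack;
  int next = 0;
  const int d0[6] = { 1, -1, 0, 0, 0, 0 };
  const int d1[6] = { 0, 0, 1, -1, 0, 0 };
  const int d2[6] = { 0, 0, 0, 0, 1, -1 };
  for (long s = 0; s < g.ncell; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      long c = stack.back(); stack.pop_back();
      int i = (int)(c % g.nc[0]);
      int j = (int)((c / g.sc[1]) % g.nc[1]);
      int k = (int)(c / g.sc[2]);
      for (int n = 0; n < 6; ++n) {
        int ii = i + d0[n], jj = j + d1[n], kk = k + d2[n];
        if (ii < 0 || jj < 0 || kk < 0 ||
            ii >= g.nc[0] || jj >= g.nc[1] || kk >= g.nc[2]) continue;
        long c2 = cidx(g, ii, jj, kk);
        if (mask[c2] && lab[c2] == 0) { lab[c2] = next; stack.push_back(c2); }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Face classification
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".classify_faces")]]
List classify_faces(IntegerVector flag, IntegerVector dim) {
  Grid g = make_grid(dim);
  List out(3);
  const int* fl = INTEGER(flag);
  for (int a = 0; a < 3; ++a) {
    IntegerVector code((R_xlen_t)g.nface[a], 0);
    for (int k = 0; k < g.nf[a][2]; ++k)
      for (int j = 0; j < g.nf[a][1]; ++j)
        for (int i = 0; i < g.nf[a][0]; ++i) {
          int p[3] = { i, j, k };
          int lo[3] = { i, j, k }; lo[a] -= 1;
          int fU = cflag(g, fl, p[0], p[1], p[2]);
          int fL = cflag(g, fl, lo[0], lo[1], lo[2]);
          // correct U for faces at upper extreme of axis a
          if (p[a] >= g.nc[a]) fU = 0;
          int c = 0;
          if (a == 1 && j == 0 && fU == 1) c = 2;                 // inlet
          else if (a == 1 && j == g.nc[1] && fL == 1) c = 3;      // outlet
          else if (fU == 1 && fL == 1) c = 1;                     // active
          code[fidx(g, a, i, j, k)] = c;
        }
    out[a] = code;
  }
  return out;
}

// ---------------------------------------------------------------------------
// SIMPLE solver
// ---------------------------------------------------------------------------

namespace {

struct Fields {
  std::vector<double> u[3];    // face velocities per axis
  std::vector<double> aP[3];   // relaxed central coefficients
  std::vector<double> dcoef[3];// A / aP for pressure correction
  std::vector<double> p;       // cell pressure
};

// one Gauss-Seidel sweep of the momentum equation for axis a over the list
// of unknown faces; returns the accumulated absolute (unrelaxed) residual
double momentum_sweep(int a, const Grid& g, const int* flag,
                      const int* code[3], Fields& F,
                      const std::vector<long>& af, const std::vector<int>& ac,
                      double d, double rho, double mu, double ur,
                      double vout, bool reverse) {
  const double A = d * d;
  const double Dg = mu * A / d;
  double resid = 0.0;
  int b = (a == 0) ? 1 : 0;
  int c = (a == 2) ? 1 : 2;
  int axes[2] = { b, c };
  const long nact = (long)af.size();
  for (long li = 0; li < nact; ++li) {
    long lidx = reverse ? (nact - 1 - li) : li;
    {
      {
        long f = af[lidx];
        int cd = code[a][f];
        int i = ac[3 * lidx], j = ac[3 * lidx + 1], k = ac[3 * lidx + 2];
        int U[3] = { i, j, k };           // upper cell == face coords
        int L[3] = { i, j, k }; L[a] -= 1; // lower cell
        bool inlet = (cd == 2);
        double ucur = F.u[a][f];
        double aPsum = 0.0, sum = 0.0;
        // --- same-axis boundaries ---
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          if (inlet && sgn == -1) {
            // ambient side of the inlet face: convective inflow carrying the
            // (lagged) face velocity; no diffusion
            double Fout = -rho * A * ucur;
            aPsum += std::max(Fout, 0.0);
            sum += std::max(-Fout, 0.0) * ucur;
            continue;
          }
          int q[3] = { i, j, k }; q[a] += sgn;
          long fn = fidx(g, a, q[0], q[1], q[2]);
          // q[a] in [0, nc[a]] guaranteed for active faces
          double uc = 0.5 * (F.u[a][f] + F.u[a][fn]);
          double Fout = sgn * rho * A * uc;
          double D = Dg;
          aPsum += D + std::max(Fout, 0.0);
          sum += (D + std::max(-Fout, 0.0)) * F.u[a][fn];
        }
        // --- cross-axis boundaries ---
        for (int t = 0; t < 2; ++t) {
          int m = axes[t];
          for (int sgn = -1; sgn <= 1; sgn += 2) {
            // convecting velocity: average of the m-faces of cells L and U on
            // side sgn
            double vmL = 0.0, vmU = 0.0;
            {
              int fc[3] = { U[0], U[1], U[2] };
              if (sgn == 1) fc[m] += 1;
              vmU = F.u[m][fidx(g, m, fc[0], fc[1], fc[2])];
            }
            if (!inlet) {
              int fc[3] = { L[0], L[1], L[2] };
              if (sgn == 1) fc[m] += 1;
              vmL = F.u[m][fidx(g, m, fc[0], fc[1], fc[2])];
            } else vmL = vmU;
            double uc = 0.5 * (vmL + vmU);
            double Fout = sgn * rho * A * uc;
            int q[3] = { i, j, k }; q[m] += sgn;
            bool ingrid = (q[m] >= 0 && q[m] < g.nf[a][m]);
            if (!ingrid) {
              if (m == 1) {
                // beyond inlet/outlet plane for a tangential velocity:
                // zero value upstream, zero-gradient downstream
                if (sgn == -1) { aPsum += std::max(Fout, 0.0); }
                else { aPsum += std::max(Fout, 0.0);
                       sum += std::max(-Fout, 0.0) * ucur; }
              } else {
                // outside the grid laterally: solid wall at d/2
                aPsum += 2.0 * Dg;
              }
              continue;
            }
            long fn = fidx(g, a, q[0], q[1], q[2]);
            int cdn = code[a][fn];
            if (cdn == 1 || cdn == 2) {
              double D = Dg;
              aPsum += D + std::max(Fout, 0.0);
              sum += (D + std::max(-Fout, 0.0)) * F.u[a][fn];
            } else if (cdn == 3) {
              double D = Dg;
              aPsum += D + std::max(Fout, 0.0);
              sum += (D + std::max(-Fout, 0.0)) * F.u[a][fn];
            } else {
              // wall or slip: inspect the two cells adjoining the neighbour
              // face location
              int cl[3] = { L[0], L[1], L[2] }; cl[m] += sgn;
              int cu[3] = { U[0], U[1], U[2] }; cu[m] += sgn;
              int fL2 = inlet ? -1 : cflag(g, flag, cl[0], cl[1], cl[2]);
              int fU2 = cflag(g, flag, cu[0], cu[1], cu[2]);
              bool anySolid = (fU2 == 0) || (!inlet && fL2 == 0);
              if (anySolid) {
                aPsum += 2.0 * Dg;   // no-slip wall at d/2, value 0, blocked
              }
              // slip: no tangential stress, no flux -> nothing
            }
          }
        }
        // pressure source
        double pterm;
        if (inlet) {
          double upos = std::max(ucur, 0.0);
          double pg = -0.5 * rho * upos * upos;  // total pressure 0 gauge
          pterm = (pg - F.p[cidx(g, U[0], U[1], U[2])]) * A;
        } else {
          pterm = (F.p[cidx(g, L[0], L[1], L[2])] -
                   F.p[cidx(g, U[0], U[1], U[2])]) * A;
        }
        resid += std::fabs(aPsum * ucur - sum - pterm);
        double aPr = aPsum / ur;
        double rhs = sum + pterm + (1.0 - ur) * aPr * ucur;
        double unew = rhs / aPr;
        F.u[a][f] = unew;
        F.aP[a][f] = aPr;
        F.dcoef[a][f] = A / aPr;
      }
    }
  }
  return resid;
}

} // namespace

// [[Rcpp::export(name = ".simple_solve")]]
List simple_solve(IntegerVector flag, IntegerVector dim, double d,
                  double rho, double mu, double vout,
                  double ur_u, double ur_p,
                  double tol_mom, double tol_cont,
                  int max_outer, int n_sweeps,
                  int cg_max, double cg_tol, bool verbose) {
  Grid g = make_grid(dim);
  const int* fl = INTEGER(flag);
  List codesL = classify_faces(flag, dim);
  const int* code[3];
  IntegerVector c0 = codesL[0], c1 = codesL[1], c2v = codesL[2];
  code[0] = INTEGER(c0); code[1] = INTEGER(c1); code[2] = INTEGER(c2v);

  // precomputed index lists: unknown faces (codes 1, 2) per axis with their
  // grid coordinates; fluid cells with their six face indices
  std::vector<long> af[3];        // face linear index
  std::vector<int> ac[3];         // packed coords (3 per face)
  for (int a = 0; a < 3; ++a) {
    for (int k = 0; k < g.nf[a][2]; ++k)
      for (int j = 0; j < g.nf[a][1]; ++j)
        for (int i = 0; i < g.nf[a][0]; ++i) {
          long f = fidx(g, a, i, j, k);
          int cd = code[a][f];
          if (cd == 1 || cd == 2) {
            af[a].push_back(f);
            ac[a].push_back(i); ac[a].push_back(j); ac[a].push_back(k);
          }
        }
  }
  std::vector<long> fcell;        // fluid cell linear indices
  std::vector<long> ff6;          // their 6 face indices (w,e,s,n,b,t)
  for (int k = 0; k < g.nc[2]; ++k)
    for (int j = 0; j < g.nc[1]; ++j)
      for (int i = 0; i < g.nc[0]; ++i) {
        long cI = cidx(g, i, j, k);
        if (fl[cI] != 1) continue;
        fcell.push_back(cI);
        ff6.push_back(fidx(g, 0, i, j, k));
        ff6.push_back(fidx(g, 0, i + 1, j, k));
        ff6.push_back(fidx(g, 1, i, j, k));
        ff6.push_back(fidx(g, 1, i, j + 1, k));
        ff6.push_back(fidx(g, 2, i, j, k));
        ff6.push_back(fidx(g, 2, i, j, k + 1));
      }

  Fields F;
  for (int a = 0; a < 3; ++a) {
    F.u[a].assign(g.nface[a], 0.0);
    F.aP[a].assign(g.nface[a], 0.0);
    F.dcoef[a].assign(g.nface[a], 0.0);
  }
  F.p.assign(g.ncell, 0.0);
  const double A = d * d;

  // initialise outlet faces and give inlet faces a gentle start
  long n_out = 0, n_in = 0;
  for (long f = 0; f < g.nface[1]; ++f) {
    if (code[1][f] == 3) { F.u[1][f] = vout; ++n_out; }
    if (code[1][f] == 2) { ++n_in; }
  }
  if (n_out == 0 || n_in == 0)
    stop("domain has no inlet or no outlet faces");
  double Q = vout * A * (double)n_out;
  double mref = rho * Q;  // mass-flux scale

  std::vector<double> mc(g.ncell), pp(g.ncell), rr(g.ncell),
      zz(g.ncell), qq(g.ncell), ss(g.ncell), diag(g.ncell);
  std::vector<double> hist_mom, hist_cont;
  bool converged = false;
  double Rm = 1.0, Rc = 1.0;

  // per-outer face connection lists for the pressure-correction solve
  const long nfl = (long)fcell.size();
  std::vector<long> conL[3], conU[3], inlC;
  std::vector<double> conC[3], inlD;
  for (int a = 0; a < 3; ++a) {
    conL[a].reserve(af[a].size()); conU[a].reserve(af[a].size());
    conC[a].reserve(af[a].size());
  }

  for (int outer = 0; outer < max_outer; ++outer) {
    // momentum sweeps
    double res[3] = { 0, 0, 0 };
    for (int s = 0; s < n_sweeps; ++s) {
      bool rev = (s % 2 == 1);
      for (int a = 0; a < 3; ++a)
        res[a] = momentum_sweep(a, g, fl, code, F, af[a], ac[a],
                                d, rho, mu, ur_u, vout, rev);
    }
    double vref = std::max(vout, 1e-30);
    Rm = (res[0] + res[1] + res[2]) / (mref * vref);

    // continuity imbalance (net mass outflow per cell)
    double csum = 0.0;
    for (long n = 0; n < nfl; ++n) {
      long cI = fcell[n];
      const long* f6 = &ff6[6 * n];
      double div = F.u[0][f6[1]] - F.u[0][f6[0]] +
                   F.u[1][f6[3]] - F.u[1][f6[2]] +
                   F.u[2][f6[5]] - F.u[2][f6[4]];
      mc[cI] = rho * A * div;
      csum += std::fabs(mc[cI]);
    }
    Rc = csum / mref;
    hist_mom.push_back(Rm);
    hist_cont.push_back(Rc);
    if (verbose && outer % 50 == 0)
      Rcout << "outer " << outer << "  Rm " << Rm << "  Rc " << Rc << "\n";
    if (Rm < tol_mom && Rc < tol_cont && outer > 2) { converged = true; break; }
    if (!std::isfinite(Rm) || !std::isfinite(Rc)) break;  // diverged

    // ---- pressure correction: CG on  Ap' = -mc ----
    for (long n = 0; n < nfl; ++n) { diag[fcell[n]] = 0.0; pp[fcell[n]] = 0.0; }
    inlC.clear(); inlD.clear();
    for (int a = 0; a < 3; ++a) {
      conL[a].clear(); conU[a].clear(); conC[a].clear();
      const long nact = (long)af[a].size();
      for (long li = 0; li < nact; ++li) {
        long f = af[a][li];
        int cd = code[a][f];
        int i = ac[a][3 * li], j = ac[a][3 * li + 1], k = ac[a][3 * li + 2];
        long cU = cidx(g, i, j, k);
        double cc = rho * A * F.dcoef[a][f];
        if (cd == 1) {
          int L[3] = { i, j, k }; L[a] -= 1;
          long cL = cidx(g, L[0], L[1], L[2]);
          diag[cL] += cc; diag[cU] += cc;
          conL[a].push_back(cL); conU[a].push_back(cU); conC[a].push_back(cc);
        } else {  // inlet
          diag[cU] += cc;
          inlC.push_back(cU); inlD.push_back(cc);
        }
      }
    }
    // CG (matrix-free product via face connection lists)
    double bnorm = 0.0;
    for (long n = 0; n < nfl; ++n) {
      long cI = fcell[n];
      rr[cI] = -mc[cI];
      bnorm += rr[cI] * rr[cI];
    }
    bnorm = std::sqrt(bnorm);
    if (bnorm > 0) {
      double rz = 0.0;
      for (long n = 0; n < nfl; ++n) {
        long cI = fcell[n];
        zz[cI] = rr[cI] / diag[cI];
        ss[cI] = zz[cI];
        rz += rr[cI] * zz[cI];
      }
      for (int it = 0; it < cg_max; ++it) {
        for (long n = 0; n < nfl; ++n) qq[fcell[n]] = 0.0;
        for (int a = 0; a < 3; ++a) {
          const long nc = (long)conC[a].size();
          const long* cl = conL[a].data();
          const long* cu = conU[a].data();
          const double* cv = conC[a].data();
          for (long n = 0; n < nc; ++n) {
            double t = cv[n] * (ss[cl[n]] - ss[cu[n]]);
            qq[cl[n]] += t; qq[cu[n]] -= t;
          }
        }
        for (size_t n = 0; n < inlC.size(); ++n)
          qq[inlC[n]] += inlD[n] * ss[inlC[n]];
        double sq = 0.0;
        for (long n = 0; n < nfl; ++n) sq += ss[fcell[n]] * qq[fcell[n]];
        if (sq <= 0) break;
        double alpha = rz / sq;
        double rnorm = 0.0;
        for (long n = 0; n < nfl; ++n) {
          long cI = fcell[n];
          pp[cI] += alpha * ss[cI];
          rr[cI] -= alpha * qq[cI];
          rnorm += rr[cI] * rr[cI];
        }
        if (std::sqrt(rnorm) < cg_tol * bnorm) break;
        double rznew = 0.0;
        for (long n = 0; n < nfl; ++n) {
          long cI = fcell[n];
          zz[cI] = rr[cI] / diag[cI];
          rznew += rr[cI] * zz[cI];
        }
        double beta = rznew / rz;
        rz = rznew;
        for (long n = 0; n < nfl; ++n) {
          long cI = fcell[n];
          ss[cI] = zz[cI] + beta * ss[cI];
        }
      }
    }
    // corrections
    for (long n = 0; n < nfl; ++n) F.p[fcell[n]] += ur_p * pp[fcell[n]];
    for (int a = 0; a < 3; ++a) {
      const long nc = (long)conC[a].size();
      long ci = 0;
      const long nact = (long)af[a].size();
      for (long li = 0; li < nact; ++li) {
        long f = af[a][li];
        if (code[a][f] == 1) {
          F.u[a][f] += F.dcoef[a][f] * (pp[conL[a][ci]] - pp[conU[a][ci]]);
          ++ci;
        }
      }
      (void)nc;
    }
    for (size_t n = 0, li = 0; li < af[1].size(); ++li) {
      long f = af[1][li];
      if (code[1][f] == 2) {
        F.u[1][f] += F.dcoef[1][f] * (0.0 - pp[inlC[n]]);
        ++n;
      }
    }
  }

  // achieved inlet flow
  double Qin = 0.0;
  for (size_t li = 0; li < af[1].size(); ++li) {
    long f = af[1][li];
    if (code[1][f] == 2) Qin += F.u[1][f] * A;
  }

  return List::create(
    _["u"] = NumericVector(F.u[0].begin(), F.u[0].end()),
    _["v"] = NumericVector(F.u[1].begin(), F.u[1].end()),
    _["w"] = NumericVector(F.u[2].begin(), F.u[2].end()),
    _["p"] = NumericVector(F.p.begin(), F.p.end()),
    _["res_mom"] = NumericVector(hist_mom.begin(), hist_mom.end()),
    _["res_cont"] = NumericVector(hist_cont.begin(), hist_cont.end()),
    _["converged"] = converged,
    _["Q_target"] = Q,
    _["Q_in"] = Qin,
    _["n_inlet"] = (double)n_in,
    _["n_outlet"] = (double)n_out);
}

// ---------------------------------------------------------------------------
// Temperature: steady advection-diffusion with Robin (mucosal) walls
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".temp_solve")]]
List temp_solve(IntegerVector flag, IntegerVector dim,
                NumericVector u, NumericVector v, NumericVector w,
                double d, double rho, double cp, double kcond,
                double h_m, double Tamb, double Tbody,
                double tol, int max_sweeps) {
  Grid g = make_grid(dim);
  const int* fl = INTEGER(flag);
  const double* vel[3] = { REAL(u), REAL(v), REAL(w) };
  const double A = d * d;
  const double Gam = kcond / cp;              // diffusion coefficient for T
  const double Dg = Gam * A / d;
  // effective wall conductance per unit area (Robin in series with half-cell
  // conduction); h_m = 0 gives an adiabatic wall
  double Ueff = (h_m > 0) ? 1.0 / (1.0 / h_m + d / (2.0 * kcond)) : 0.0;
  const double wallS = Ueff * A / cp;

  std::vector<double> T(g.ncell, Tamb);
  double scale = 0.0;  // energy scale: sum of inlet mass flux * (Tbody-Tamb)
  for (int k = 0; k < g.nf[1][2]; ++k)
    for (int i = 0; i < g.nf[1][0]; ++i) {
      long f = fidx(g, 1, i, 0, k);
      if (cflag(g, fl, i, 0, k) == 1)
        scale += std::fabs(rho * A * vel[1][f]);
    }
  scale = std::max(scale * (Tbody - Tamb), 1e-30);

  double resid = 1e30;
  int sweeps = 0;
  const int dII[6] = { -1, 1, 0, 0, 0, 0 };
  const int dJJ[6] = { 0, 0, -1, 1, 0, 0 };
  const int dKK[6] = { 0, 0, 0, 0, -1, 1 };
  const int axn[6] = { 0, 0, 1, 1, 2, 2 };
  const int sgn6[6] = { -1, 1, -1, 1, -1, 1 };
  for (sweeps = 0; sweeps < max_sweeps; ++sweeps) {
    bool rev = (sweeps % 2 == 1);
    resid = 0.0;
    for (int kk = 0; kk < g.nc[2]; ++kk) {
      int k = rev ? g.nc[2] - 1 - kk : kk;
      for (int jj = 0; jj < g.nc[1]; ++jj) {
        int j = rev ? g.nc[1] - 1 - jj : jj;
        for (int i = 0; i < g.nc[0]; ++i) {
          long cI = cidx(g, i, j, k);
          if (fl[cI] != 1) continue;
          double aP = 0.0, sum = 0.0;
          for (int n = 0; n < 6; ++n) {
            int a = axn[n], sg = sgn6[n];
            int q0 = i + dII[n], q1 = j + dJJ[n], q2 = k + dKK[n];
            // face of cell on this side
            int fc[3] = { i, j, k };
            if (sg == 1) fc[a] += 1;
            double uf = vel[a][fidx(g, a, fc[0], fc[1], fc[2])];
            double Fout = sg * rho * A * uf;
            int nf = cflag(g, fl, q0, q1, q2);
            bool yin = (a == 1 && q1 < 0);
            bool yout = (a == 1 && q1 >= g.nc[1]);
            if (yin) {
              // inlet: advective inflow at ambient temperature
              aP += std::max(Fout, 0.0);
              sum += std::max(-Fout, 0.0) * Tamb;
            } else if (yout) {
              // outlet: advection only, zero-gradient
              aP += std::max(Fout, 0.0);
            } else if (nf == 1) {
              aP += Dg + std::max(Fout, 0.0);
              sum += (Dg + std::max(-Fout, 0.0)) * T[cidx(g, q0, q1, q2)];
            } else if (nf == 0) {
              // mucosal wall: Robin source
              aP += wallS;
              sum += wallS * Tbody;
            }
            // slip (nf == 2): adiabatic, nothing
          }
          double Told = T[cI];
          resid += std::fabs(aP * Told - sum);
          T[cI] = sum / aP;
        }
      }
    }
    if (resid / scale < tol) { ++sweeps; break; }
  }
  return List::create(_["T"] = NumericVector(T.begin(), T.end()),
                      _["residual"] = resid / scale,
                      _["sweeps"] = sweeps);
}

// ---------------------------------------------------------------------------
// Wall faces and per-face fields
// ---------------------------------------------------------------------------

// Enumerates mucosal wall faces (fluid cell face adjacent to a solid cell or
// to the lateral outside of the grid; slip cells and the inlet/outlet planes
// are excluded) and evaluates one-sided wall shear, wall temperature and heat
// flux. Returns a matrix with columns:
// i, j, k (1-based cell), axis (1..3), sgn, cx, cy, cz (face centroid, voxel
// units), taux, tauy, tauz, taumag, Tcell, Tw, q
// [[Rcpp::export(name = ".wall_fields")]]
NumericMatrix wall_fields(IntegerVector flag, IntegerVector dim,
                          NumericVector u, NumericVector v, NumericVector w,
                          double d, double mu, double kcond,
                          double h_m, double Tbody,
                          Nullable<NumericVector> Tfield) {
  Grid g = make_grid(dim);
  const int* fl = INTEGER(flag);
  const double* vel[3] = { REAL(u), REAL(v), REAL(w) };
  bool hasT = Tfield.isNotNull();
  NumericVector Tv;
  const double* T = nullptr;
  if (hasT) { Tv = Tfield.get(); T = REAL(Tv); }

  const int dII[6] = { -1, 1, 0, 0, 0, 0 };
  const int dJJ[6] = { 0, 0, -1, 1, 0, 0 };
  const int dKK[6] = { 0, 0, 0, 0, -1, 1 };
  const int axn[6] = { 0, 0, 1, 1, 2, 2 };
  const int sgn6[6] = { -1, 1, -1, 1, -1, 1 };

  // first count
  long nw = 0;
  for (int k = 0; k < g.nc[2]; ++k)
    for (int j = 0; j < g.nc[1]; ++j)
      for (int i = 0; i < g.nc[0]; ++i) {
        if (fl[cidx(g, i, j, k)] != 1) continue;
        for (int n = 0; n < 6; ++n) {
          int q0 = i + dII[n], q1 = j + dJJ[n], q2 = k + dKK[n];
          if (axn[n] == 1 && (q1 < 0 || q1 >= g.nc[1])) continue; // in/outlet
          if (cflag(g, fl, q0, q1, q2) == 0) ++nw;
        }
      }
  NumericMatrix out(nw, 15);
  long r = 0;
  for (int k = 0; k < g.nc[2]; ++k)
    for (int j = 0; j < g.nc[1]; ++j)
      for (int i = 0; i < g.nc[0]; ++i) {
        long cI = cidx(g, i, j, k);
        if (fl[cI] != 1) continue;
        // cell-centre velocity components (average of opposing faces)
        double uc[3];
        uc[0] = 0.5 * (vel[0][fidx(g, 0, i, j, k)] + vel[0][fidx(g, 0, i + 1, j, k)]);
        uc[1] = 0.5 * (vel[1][fidx(g, 1, i, j, k)] + vel[1][fidx(g, 1, i, j + 1, k)]);
        uc[2] = 0.5 * (vel[2][fidx(g, 2, i, j, k)] + vel[2][fidx(g, 2, i, j, k + 1)]);
        for (int n = 0; n < 6; ++n) {
          int a = axn[n], sg = sgn6[n];
          int q0 = i + dII[n], q1 = j + dJJ[n], q2 = k + dKK[n];
          if (a == 1 && (q1 < 0 || q1 >= g.nc[1])) continue;
          if (cflag(g, fl, q0, q1, q2) != 0) continue;
          // tangential one-sided shear from cell-centre velocity at d/2
          double tau[3] = { 0, 0, 0 };
          for (int m = 0; m < 3; ++m)
            if (m != a) tau[m] = mu * uc[m] / (0.5 * d);
          double tmag = std::sqrt(tau[0]*tau[0] + tau[1]*tau[1] + tau[2]*tau[2]);
          double Tc = hasT ? T[cI] : NA_REAL;
          double Tw = NA_REAL, qf = NA_REAL;
          if (hasT) {
            if (h_m > 0) {
              double c2 = 2.0 * kcond / d;
              Tw = (h_m * Tbody + c2 * Tc) / (h_m + c2);
              qf = h_m * (Tbody - Tw);
            } else { Tw = Tc; qf = 0.0; }
          }
          out(r, 0) = i + 1; out(r, 1) = j + 1; out(r, 2) = k + 1;
          out(r, 3) = a + 1; out(r, 4) = sg;
          out(r, 5) = i + 0.5 + (a == 0 ? 0.5 * sg : 0.0);
          out(r, 6) = j + 0.5 + (a == 1 ? 0.5 * sg : 0.0);
          out(r, 7) = k + 0.5 + (a == 2 ? 0.5 * sg : 0.0);
          out(r, 8) = tau[0]; out(r, 9) = tau[1]; out(r, 10) = tau[2];
          out(r, 11) = tmag;
          out(r, 12) = Tc; out(r, 13) = Tw; out(r, 14) = qf;
          ++r;
        }
      }
  colnames(out) = CharacterVector::create(
    "i", "j", "k", "axis", "sgn", "cx", "cy", "cz",
    "taux", "tauy", "tauz", "taumag", "Tcell", "Tw", "q");
  return out;
}
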
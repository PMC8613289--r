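// Semi-implicit finite-volume engine for the two-compartment
// nucleocytoplasmic actin model.
//
// Per step (Lie splitting, documented order):
//   1. explicit mass-action reaction increments, cell-local per compartment
//   2. explicit membrane transfer across nuclear faces (flux * face length,
//      exact pairwise conservation, per-face donor limiting)
//   3. implicit diffusion per species: dimension-split backward-Euler line
//      solves (x sweep then y sweep) with reflecting ends on every
//      compartment segment; each tridiagonal matrix has unit column sums so
//      mass is conserved to round-off.
//
// Fields are stored on the full nx*ny grid (column-major, index ix + nx*iy)
// and are zero outside their compartment.

#include <Rcpp.h>
#include <vector>
#include <set>
#include <cmath>

using namespace Rcpp;

static const int NSP = 13;
// fixed species order, mirrored by nucactin_species() on the R side
enum SpeciesIdx {
  iGc = 0, iFc, iCc, iXic, iPc, iUc, iThc, iEc,
  iGn, iCn, iXin, iPn, iUn
};

struct Kin {
  double gGc, gFc;
  double aXic, gXic, aThc, gThc, aUc, gUc;
  double aXin, gXin, aUn, gUn;
  double mu1, mu2, gEc;
  double bPc, bPn, bCc, bCn, bXic, bUn;
};

static double getp(const List& par, const char* nm) {
  if (!par.containsElementNamed(nm)) stop("missing kinetic parameter '%s'", nm);
  return as<double>(par[nm]);
}

static Kin read_kin(const List& par) {
  Kin k;
  k.gGc  = getp(par, "gamma_Gc");     k.gFc  = getp(par, "gamma_Fc");
  k.aXic = getp(par, "alpha_Xi_c");   k.gXic = getp(par, "gamma_Xi_c");
  k.aThc = getp(par, "alpha_Theta_c");k.gThc = getp(par, "gamma_Theta_c");
  k.aUc  = getp(par, "alpha_Ups_c");  k.gUc  = getp(par, "gamma_Ups_c");
  k.aXin = getp(par, "alpha_Xi_n");   k.gXin = getp(par, "gamma_Xi_n");
  k.aUn  = getp(par, "alpha_Ups_n");  k.gUn  = getp(par, "gamma_Ups_n");
  k.mu1  = getp(par, "mu1");          k.mu2  = getp(par, "mu2");
  k.gEc  = getp(par, "gamma_Ec");
  k.bPc  = getp(par, "beta_Pc");      k.bPn  = getp(par, "beta_Pn");
  k.bCc  = getp(par, "beta_Cc");      k.bCn  = getp(par, "beta_Cn");
  k.bXic = getp(par, "beta_Xi_c");    k.bUn  = getp(par, "beta_Ups_n");
  return k;
}

struct Seg { int start; int n; };

// contiguous same-compartment runs along x (stride 1) and y (stride nx)
static void build_segments(const int* mask, int nx, int ny, int comp,
                           std::vector<Seg>& segx, std::vector<Seg>& segy) {
  for (int iy = 0; iy < ny; ++iy) {
    int run = -1;
    for (int ix = 0; ix < nx; ++ix) {
      int idx = ix + nx * iy;
      if (mask[idx] == comp) {
        if (run < 0) run = idx;
      } else if (run >= 0) {
        segx.push_back({run, idx - run});
        run = -1;
      }
    }
    if (run >= 0) segx.push_back({run, nx + nx * iy - run});
  }
  for (int ix = 0; ix < nx; ++ix) {
    int run = -1, len = 0;
    for (int iy = 0; iy < ny; ++iy) {
      int idx = ix + nx * iy;
      if (mask[idx] == comp) {
        if (run < 0) { run = idx; len = 0; }
        ++len;
      } else if (run >= 0) {
        segy.push_back({run, len});
        run = -1;
      }
    }
    if (run >= 0) segy.push_back({run, len});
  }
}

// Backward-Euler tridiagonal solve of (I - a L) u = b with reflecting ends:
// diag 1+a at ends, 1+2a inside, off-diagonals -a. The forward-elimination
// coefficients depend only on the row index (and, for the last row, the
// segment length), so they are precomputed once per diffusion coefficient;
// the per-cell solve is then division-free.
struct LineSolver {
  double a = 0.0;
  std::vector<double> cp;         // generic-row c' coefficients
  std::vector<double> minv;       // generic-row inverse pivots
  std::vector<double> mlast_inv;  // last-row inverse pivot per length n
  void build(double a_, int maxn) {
    a = a_;
    if (a == 0.0 || maxn < 2) return;
    cp.resize(maxn); minv.resize(maxn); mlast_inv.resize(maxn + 1, 0.0);
    minv[0] = 1.0 / (1.0 + a);
    cp[0] = -a * minv[0];
    for (int i = 1; i < maxn; ++i) {
      double m = 1.0 + 2.0 * a + a * cp[i - 1];
      minv[i] = 1.0 / m;
      cp[i] = -a * minv[i];
    }
    for (int n = 2; n <= maxn; ++n)
      mlast_inv[n] = 1.0 / (1.0 + a + a * cp[n - 2]);
  }
  void solve(double* u, int n, int stride, std::vector<double>& dp) const {
    if (n == 1 || a == 0.0) return;
    if ((int)dp.size() < n) dp.resize(n);
    dp[0] = u[0] * minv[0];
    for (int i = 1; i < n - 1; ++i)
      dp[i] = (u[(size_t)i * stride] + a * dp[i - 1]) * minv[i];
    dp[n - 1] = (u[(size_t)(n - 1) * stride] + a * dp[n - 2]) * mlast_inv[n];
    u[(size_t)(n - 1) * stride] = dp[n - 1];
    for (int i = n - 2; i >= 0; --i)
      u[(size_t)i * stride] = dp[i] - cp[i] * u[(size_t)(i + 1) * stride];
  }
};

static void diffuse_field(double* f, const LineSolver& ls,
                          const std::vector<Seg>& segx,
                          const std::vector<Seg>& segy, int nx,
                          std::vector<double>& dp) {
  if (ls.a == 0.0) return;
  for (const Seg& s : segx) ls.solve(f + s.start, s.n, 1, dp);
  for (const Seg& s : segy) ls.solve(f + s.start, s.n, nx, dp);
}

// [[Rcpp::export]]
NumericVector cpp_diffuse(NumericVector field, IntegerVector mask,
                          int nx, int ny, int compartment,
                          double D, double dt, double h, int n_steps) {
  if (field.size() != (R_xlen_t)nx * ny || mask.size() != field.size())
    stop("field/mask size does not match grid");
  NumericVector out = clone(field);
  if (D < 0) stop("negative diffusion coefficient");
  std::vector<Seg> segx, segy;
  build_segments(INTEGER(mask), nx, ny, compartment, segx, segy);
  LineSolver ls;
  ls.build(D * dt / (h * h), std::max(nx, ny));
  std::vector<double> dp;
  double* f = REAL(out);
  for (int s = 0; s < n_steps; ++s) diffuse_field(f, ls, segx, segy, nx, dp);
  return out;
}

struct Faces {
  std::vector<int> ci;  // cytoplasm cell index
  std::vector<int> ni;  // nucleus cell index
};

static Faces build_faces(const int* mask, int nx, int ny) {
  Faces fc;
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      int idx = ix + nx * iy;
      if (ix + 1 < nx) {
        int jdx = idx + 1;
        if (mask[idx] == 1 && mask[jdx] == 2) { fc.ci.push_back(idx); fc.ni.push_back(jdx); }
        if (mask[idx] == 2 && mask[jdx] == 1) { fc.ci.push_back(jdx); fc.ni.push_back(idx); }
      }
      if (iy + 1 < ny) {
        int jdx = idx + nx;
        if (mask[idx] == 1 && mask[jdx] == 2) { fc.ci.push_back(idx); fc.ni.push_back(jdx); }
        if (mask[idx] == 2 && mask[jdx] == 1) { fc.ci.push_back(jdx); fc.ni.push_back(idx); }
      }
    }
  }
  return fc;
}

// Exchange one species pair across all nuclear faces. Fluxes are evaluated
// first, from the beginning-of-substep state, then applied (flux > 0 means
// into the nucleus); a donor cell about to be overdrawn has that face's
// transfer clamped to empty it exactly, counted in `limited`.
struct FaceFlux {
  std::vector<double> flux;
  void exchange(double* fcyt, double* fnuc, const Faces& faces, double r,
                long long& limited) {
    const int nf = (int)faces.ci.size();
    for (int i = 0; i < nf; ++i) {
      int ci = faces.ci[i], ni = faces.ni[i];
      double fl = flux[i];
      if (fl > 0.0) {
        double amt = fl * r;
        if (amt > fcyt[ci]) { amt = fcyt[ci]; ++limited; }
        fcyt[ci] -= amt; fnuc[ni] += amt;
      } else if (fl < 0.0) {
        double amt = -fl * r;
        if (amt > fnuc[ni]) { amt = fnuc[ni]; ++limited; }
        fnuc[ni] -= amt; fcyt[ci] += amt;
      }
    }
  }
};

// [[Rcpp::export]]
List cpp_run(List fields_in, IntegerVector mask, int nx, int ny, double h,
             List par, NumericVector D, double dt, int n_steps,
             int output_every, IntegerVector snapshot_steps,
             double pos_tol, bool ec_first_order, double t0) {
  if (fields_in.size() != NSP) stop("expected %d species fields", NSP);
  Kin k = read_kin(par);
  if (D.size() != NSP) stop("expected %d diffusion coefficients", NSP);

  const int* msk = INTEGER(mask);
  const size_t ncell = (size_t)nx * ny;

  // working copies
  std::vector<NumericVector> F(NSP);
  std::vector<double*> f(NSP);
  for (int s = 0; s < NSP; ++s) {
    NumericVector v = as<NumericVector>(fields_in[s]);
    if ((size_t)v.size() != ncell) stop("field %d has wrong size", s + 1);
    F[s] = clone(v);
    f[s] = REAL(F[s]);
  }

  // compartment cell lists
  std::vector<int> cells_c, cells_n;
  for (size_t i = 0; i < ncell; ++i) {
    if (msk[i] == 1) cells_c.push_back((int)i);
    else if (msk[i] == 2) cells_n.push_back((int)i);
  }
  if (cells_c.empty() || cells_n.empty())
    stop("domain must contain at least one cytoplasm and one nucleus cell");

  std::vector<Seg> segx_c, segy_c, segx_n, segy_n;
  build_segments(msk, nx, ny, 1, segx_c, segy_c);
  build_segments(msk, nx, ny, 2, segx_n, segy_n);
  Faces faces = build_faces(msk, nx, ny);
  const int nfaces = (int)faces.ci.size();

  const double r = dt / h;        // converts flux density to concentration
  const double cellA = h * h;

  // recording layout
  std::vector<int> rec_steps;
  rec_steps.push_back(0);
  for (int s = 1; s <= n_steps; ++s)
    if (s % output_every == 0 || s == n_steps) rec_steps.push_back(s);
  const int ncol = 9;
  NumericMatrix summary((int)rec_steps.size(), ncol);
  CharacterVector cn = CharacterVector::create(
    "t", "mean_Gn", "mean_Gc", "total_Fc", "total_Theta_c",
    "total_actin", "total_cofilin", "total_profilin", "total_E");
  colnames(summary) = cn;

  std::set<int> snap_at(snapshot_steps.begin(), snapshot_steps.end());
  List snapshots;
  std::vector<double> snap_times;

  long long clip_events = 0, limited = 0;
  std::vector<double> dp;
  FaceFlux fluxP, fluxC, fluxXi, fluxU;
  fluxP.flux.resize(nfaces); fluxC.flux.resize(nfaces);
  fluxXi.flux.resize(nfaces); fluxU.flux.resize(nfaces);

  auto sum_over = [&](int sp, const std::vector<int>& cells) {
    double tot = 0.0;
    for (int i : cells) tot += f[sp][i];
    return tot;
  };

  auto record_row = [&](int row, int stepno) {
    double sGc = sum_over(iGc, cells_c), sFc = sum_over(iFc, cells_c);
    double sCc = sum_over(iCc, cells_c), sXic = sum_over(iXic, cells_c);
    double sPc = sum_over(iPc, cells_c), sUc = sum_over(iUc, cells_c);
    double sThc = sum_over(iThc, cells_c), sEc = sum_over(iEc, cells_c);
    double sGn = sum_over(iGn, cells_n), sCn = sum_over(iCn, cells_n);
    double sXin = sum_over(iXin, cells_n), sPn = sum_over(iPn, cells_n);
    double sUn = sum_over(iUn, cells_n);
    if (!std::isfinite(sGc) || !std::isfinite(sGn))
      stop("non-finite field values at step %d", stepno);
    summary(row, 0) = t0 + stepno * dt;
    summary(row, 1) = sGn / (double)cells_n.size();
    summary(row, 2) = sGc / (double)cells_c.size();
    summary(row, 3) = sFc * cellA;
    summary(row, 4) = sThc * cellA;
    summary(row, 5) = (sGc + sFc + sXic + sUc + sGn + sXin + sUn) * cellA;
    summary(row, 6) = (sCc + sXic + sThc + sCn + sXin) * cellA;
    summary(row, 7) = (sPc + sUc + sPn + sUn) * cellA;
    summary(row, 8) = sEc * cellA;
  };

  auto take_snapshot = [&](int stepno) {
    List snap(NSP);
    for (int s = 0; s < NSP; ++s) snap[s] = clone(F[s]);
    snapshots.push_back(snap);
    snap_times.push_back(t0 + stepno * dt);
  };

  int rec_row = 0;
  record_row(rec_row++, 0);
  if (snap_at.count(0)) take_snapshot(0);

  // per-species diffusion prep: skip D == 0
  std::vector<LineSolver> ls(NSP);
  for (int s = 0; s < NSP; ++s)
    ls[s].build(D[s] * dt / (h * h), std::max(nx, ny));

  const double round_floor = -1e-13;

  for (int step = 1; step <= n_steps; ++step) {
    // (1) explicit reactions, cytoplasm
    for (int i : cells_c) {
      double G = f[iGc][i], Fa = f[iFc][i], C = f[iCc][i], Xi = f[iXic][i];
      double P = f[iPc][i], U = f[iUc][i], Th = f[iThc][i], E = f[iEc][i];
      double pol  = k.gGc * (1.0 + k.mu1 * E) * G;
      double dep  = k.gFc * Fa;
      double aXi  = k.aXic * G * C,  dXi  = k.gXic * Xi;
      double aU   = k.aUc * G * P,   dU   = k.gUc * U;
      double ph   = k.aThc * (1.0 + k.mu2 * E) * C, deph = k.gThc * Th;
      f[iGc][i]  += dt * (dep - pol + dXi - aXi + dU - aU);
      f[iFc][i]  += dt * (pol - dep);
      f[iCc][i]  += dt * (dXi - aXi - ph + deph);
      f[iXic][i] += dt * (aXi - dXi);
      f[iPc][i]  += dt * (dU - aU);
      f[iUc][i]  += dt * (aU - dU);
      f[iThc][i] += dt * (ph - deph);
      f[iEc][i]  += dt * (ec_first_order ? -k.gEc * E : -k.gEc);
    }
    // (1) explicit reactions, nucleus
    for (int i : cells_n) {
      double G = f[iGn][i], C = f[iCn][i], Xi = f[iXin][i];
      double P = f[iPn][i], U = f[iUn][i];
      double aXi = k.aXin * G * C, dXi = k.gXin * Xi;
      double aU  = k.aUn * G * P,  dU  = k.gUn * U;
      f[iGn][i]  += dt * (dXi - aXi + dU - aU);
      f[iCn][i]  += dt * (dXi - aXi);
      f[iXin][i] += dt * (aXi - dXi);
      f[iPn][i]  += dt * (dU - aU);
      f[iUn][i]  += dt * (aU - dU);
    }

    // (2) explicit membrane transfer on nuclear faces
    for (int fi = 0; fi < nfaces; ++fi) {
      int ci = faces.ci[fi], ni = faces.ni[fi];
      fluxP.flux[fi]  = k.bPc * f[iPc][ci] - k.bPn * f[iPn][ni];
      fluxC.flux[fi]  = k.bCc * f[iCc][ci] - k.bCn * f[iCn][ni];
      fluxXi.flux[fi] = k.bXic * f[iXic][ci];            // into nucleus
      fluxU.flux[fi]  = -k.bUn * f[iUn][ni];             // into cytoplasm
    }
    fluxP.exchange(f[iPc], f[iPn], faces, r, limited);
    fluxC.exchange(f[iCc], f[iCn], faces, r, limited);
    fluxXi.exchange(f[iXic], f[iXin], faces, r, limited);
    fluxU.exchange(f[iUc], f[iUn], faces, r, limited);

    // (3) implicit diffusion
    for (int s = 0; s < NSP; ++s) {
      if (ls[s].a == 0.0) continue;
      if (s < iGn) diffuse_field(f[s], ls[s], segx_c, segy_c, nx, dp);
      else         diffuse_field(f[s], ls[s], segx_n, segy_n, nx, dp);
    }

    // positivity hygiene
    for (int s = 0; s < NSP; ++s) {
      const std::vector<int>& cells = (s < iGn) ? cells_c : cells_n;
      double* fs = f[s];
      for (int i : cells) {
        double v = fs[i];
        if (v < 0.0) {
          if (v < -pos_tol)
            stop("species %d fell below -positivity_tolerance (%g) at step %d",
                 s + 1, v, step);
          if (v < round_floor) ++clip_events;
          fs[i] = 0.0;
        }
      }
    }

    if (step % output_every == 0 || step == n_steps) record_row(rec_row++, step);
    if (snap_at.count(step)) take_snapshot(step);
  }

  List final_fields(NSP);
  for (int s = 0; s < NSP; ++s) final_fields[s] = F[s];

  return List::create(
    _["summary"] = summary,
    _["snapshots"] = snapshots,
    _["snapshot_times"] = wrap(snap_times),
    _["final_fields"] = final_fields,
    _["t_end"] = t0 + n_steps * dt,
    _["clip_events"] = (double)clip_events,
    _["limited_fluxes"] = (double)limited);
}
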
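// DPD engine core: cell-list pair search, soft conservative forces,
// pairwise random/dissipative thermostat, harmonic bonds, cosine angle
// bending, modified velocity-Verlet integration, and Berendsen-style
// anisotropic pressure coupling on the two axes perpendicular to the tube.
// All quantities in reduced units (lengths in rC, energies in kBT, m = 1).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>

using namespace Rcpp;

// minimum image for displacements between wrapped coordinates (|d| < L)
static inline double minimg(double d, double L) {
  if (d > 0.5 * L) return d - L;
  if (d < -0.5 * L) return d + L;
  return d;
}

static inline double wrap01(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L; // guard against floor rounding at the boundary
  if (x < 0.0) x += L;
  return x;
}

// Visit every unordered pair (i<j implied by traversal) with r2 < rc2.
// Linked-cell search when the box admits >= 3 cells per dimension,
// otherwise an exhaustive minimum-image double loop.
template <typename F>
static void for_each_pair(const std::vector<double>& px,
                          const std::vector<double>& py,
                          const std::vector<double>& pz,
                          const double box[3], double rc, F&& visit) {
  const int n = (int)px.size();
  const double rc2 = rc * rc;
  int nc[3];
  for (int d = 0; d < 3; ++d) nc[d] = (int)std::floor(box[d] / rc);

  if (nc[0] < 3 || nc[1] < 3 || nc[2] < 3 || n < 32) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = minimg(px[i] - px[j], box[0]);
        double dy = minimg(py[i] - py[j], box[1]);
        double dz = minimg(pz[i] - pz[j], box[2]);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < rc2) visit(i, j, dx, dy, dz, r2);
      }
    }
    return;
  }

  const int ncx = nc[0], ncy = nc[1], ncz = nc[2];
  const int ncells = ncx * ncy * ncz;
  std::vector<int> head(ncells, -1), nxt(n, -1);
  std::vector<int> cix(n), ciy(n), ciz(n);
  for (int i = 0; i < n; ++i) {
    int cx = (int)(wrap01(px[i], box[0]) / box[0] * ncx); if (cx >= ncx) cx = ncx - 1;
    int cy = (int)(wrap01(py[i], box[1]) / box[1] * ncy); if (cy >= ncy) cy = ncy - 1;
    int cz = (int)(wrap01(pz[i], box[2]) / box[2] * ncz); if (cz >= ncz) cz = ncz - 1;
    cix[i] = cx; ciy[i] = cy; ciz[i] = cz;
    int c = (cx * ncy + cy) * ncz + cz;
    nxt[i] = head[c];
    head[c] = i;
  }

  // half stencil: self cell (i<j) plus 13 forward neighbor offsets
  static const int off[13][3] = {
    {1,0,0},{1,1,0},{1,-1,0},{0,1,0},
    {1,0,1},{1,1,1},{1,-1,1},{0,1,1},{0,0,1},
    {1,0,-1},{1,1,-1},{1,-1,-1},{0,1,-1}
  };

  for (int cx = 0; cx < ncx; ++cx)
  for (int cy = 0; cy < ncy; ++cy)
  for (int cz = 0; cz < ncz; ++cz) {
    int c = (cx * ncy + cy) * ncz + cz;
    for (int i = head[c]; i >= 0; i = nxt[i]) {
      for (int j = nxt[i]; j >= 0; j = nxt[j]) {
        double dx = minimg(px[i] - px[j], box[0]);
        double dy = minimg(py[i] - py[j], box[1]);
        double dz = minimg(pz[i] - pz[j], box[2]);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < rc2) visit(i, j, dx, dy, dz, r2);
      }
    }
    for (int s = 0; s < 13; ++s) {
      int ox = (cx + off[s][0] + ncx) % ncx;
      int oy = (cy + off[s][1] + ncy) % ncy;
      int oz = (cz + off[s][2] + ncz) % ncz;
      int c2 = (ox * ncy + oy) * ncz + oz;
      for (int i = head[c]; i >= 0; i = nxt[i]) {
        for (int j = head[c2]; j >= 0; j = nxt[j]) {
          double dx = minimg(px[i] - px[j], box[0]);
          double dy = minimg(py[i] - py[j], box[1]);
          double dz = minimg(pz[i] - pz[j], box[2]);
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 < rc2) visit(i, j, dx, dy, dz, r2);
        }
      }
    }
  }
}

struct BondTable {
  std::vector<int> bi, bj;
  std::vector<double> bk, br0;
  std::vector<int> ai, aj, ak; // aj is the central bead
  std::vector<double> akang, ath0;
  // directly bonded partners of each bead (1-2 exclusion from nonbonded
  // forces; at most 4 partners per bead in this model)
  std::vector<int> adj;
  void build_adj(int n) {
    adj.assign((size_t)n * 4, -1);
    for (size_t b = 0; b < bi.size(); ++b) {
      for (int two = 0; two < 2; ++two) {
        int u = two ? bj[b] : bi[b], v = two ? bi[b] : bj[b];
        for (int s = 0; s < 4; ++s) {
          if (adj[(size_t)u * 4 + s] < 0) { adj[(size_t)u * 4 + s] = v; break; }
        }
      }
    }
  }
  inline bool excluded(int i, int j) const {
    if (adj.empty()) return false;
    const int* a4 = &adj[(size_t)i * 4];
    return a4[0] == j || a4[1] == j || a4[2] == j || a4[3] == j;
  }
};

// Conservative + bonded forces always; random/dissipative (thermostat)
// only between mobile-mobile pairs and only when thermo = true.
// Virial accumulates conservative + bonded contributions per axis.
struct ForceEval {
  std::vector<double> fx, fy, fz;
  double W[3];
  long n_coincident;
};

static void compute_forces(const std::vector<double>& px,
                           const std::vector<double>& py,
                           const std::vector<double>& pz,
                           const std::vector<double>& vx,
                           const std::vector<double>& vy,
                           const std::vector<double>& vz,
                           const std::vector<int>& type,
                           const std::vector<char>& frozen,
                           const double box[3],
                           const double* a, int ntypes,
                           double gamma, double sigma, double inv_sqrt_dt,
                           const BondTable& bt,
                           bool thermo,
                           std::mt19937_64& rng,
                           ForceEval& out) {
  const int n = (int)px.size();
  out.fx.assign(n, 0.0); out.fy.assign(n, 0.0); out.fz.assign(n, 0.0);
  out.W[0] = out.W[1] = out.W[2] = 0.0;
  out.n_coincident = 0;
  std::normal_distribution<double> gauss(0.0, 1.0);

  double* fx = out.fx.data();
  double* fy = out.fy.data();
  double* fz = out.fz.data();
  double* W = out.W;
  long* ncoin = &out.n_coincident;

  for_each_pair(px, py, pz, box, 1.0, [&](int i, int j, double dx, double dy,
                                          double dz, double r2) {
    bool fi = frozen[i] != 0, fj = frozen[j] != 0;
    if (fi && fj) return;
    if (bt.excluded(i, j)) return; // bonded pairs: harmonic term only
    double r = std::sqrt(r2);
    double ex, ey, ez;
    if (r < 1e-12) { // coincident beads: deterministic fallback direction
      ex = 1.0; ey = 0.0; ez = 0.0; r = 0.0;
      ++(*ncoin);
    } else {
      ex = dx / r; ey = dy / r; ez = dz / r;
    }
    double w = 1.0 - r; // (1 - r/rc) with rc = 1
    double aij = a[type[i] * ntypes + type[j]];
    double fc = aij * w;
    double fxx = fc * ex, fyy = fc * ey, fzz = fc * ez;
    if (thermo && !fi && !fj) {
      double dvx = vx[i] - vx[j], dvy = vy[i] - vy[j], dvz = vz[i] - vz[j];
      double vdote = dvx * ex + dvy * ey + dvz * ez;
      double fd = -gamma * w * w * vdote;
      double fr = sigma * w * gauss(rng) * inv_sqrt_dt;
      double ft = fd + fr;
      fx[i] += ft * ex; fy[i] += ft * ey; fz[i] += ft * ez;
      fx[j] -= ft * ex; fy[j] -= ft * ey; fz[j] -= ft * ez;
    }
    fx[i] += fxx; fy[i] += fyy; fz[i] += fzz;
    fx[j] -= fxx; fy[j] -= fyy; fz[j] -= fzz;
    W[0] += fxx * dx; W[1] += fyy * dy; W[2] += fzz * dz;
  });

  // harmonic bonds u = 1/2 k (r - r0)^2
  for (size_t b = 0; b < bt.bi.size(); ++b) {
    int i = bt.bi[b], j = bt.bj[b];
    double dx = minimg(px[i] - px[j], box[0]);
    double dy = minimg(py[i] - py[j], box[1]);
    double dz = minimg(pz[i] - pz[j], box[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) { ++(*ncoin); continue; }
    double fmag = -bt.bk[b] * (r - bt.br0[b]) / r; // along (ri - rj)
    double fxx = fmag * dx, fyy = fmag * dy, fzz = fmag * dz;
    fx[i] += fxx; fy[i] += fyy; fz[i] += fzz;
    fx[j] -= fxx; fy[j] -= fyy; fz[j] -= fzz;
    W[0] += fxx * dx; W[1] += fyy * dy; W[2] += fzz * dz;
  }

  // angle bending u = 1/2 k (1 - cos(theta - theta0)), j central
  for (size_t t = 0; t < bt.ai.size(); ++t) {
    int i = bt.ai[t], j = bt.aj[t], k = bt.ak[t];
    double r1x = minimg(px[i] - px[j], box[0]);
    double r1y = minimg(py[i] - py[j], box[1]);
    double r1z = minimg(pz[i] - pz[j], box[2]);
    double r2x = minimg(px[k] - px[j], box[0]);
    double r2y = minimg(py[k] - py[j], box[1]);
    double r2z = minimg(pz[k] - pz[j], box[2]);
    double n1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
    double n2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
    if (n1 < 1e-12 || n2 < 1e-12) { ++(*ncoin); continue; }
    double c = (r1x * r2x + r1y * r2y + r1z * r2z) / (n1 * n2);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double theta = std::acos(c);
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-8) s = 1e-8; // colinear regularization
    double dUdtheta = 0.5 * bt.akang[t] * std::sin(theta - bt.ath0[t]);
    double pref = dUdtheta / s;
    double inv12 = 1.0 / (n1 * n2);
    double fix = pref * (r2x * inv12 - c * r1x / (n1 * n1));
    double fiy = pref * (r2y * inv12 - c * r1y / (n1 * n1));
    double fiz = pref * (r2z * inv12 - c * r1z / (n1 * n1));
    double fkx = pref * (r1x * inv12 - c * r2x / (n2 * n2));
    double fky = pref * (r1y * inv12 - c * r2y / (n2 * n2));
    double fkz = pref * (r1z * inv12 - c * r2z / (n2 * n2));
    fx[i] += fix; fy[i] += fiy; fz[i] += fiz;
    fx[k] += fkx; fy[k] += fky; fz[k] += fkz;
    fx[j] -= fix + fkx; fy[j] -= fiy + fky; fz[j] -= fiz + fkz;
    W[0] += fix * r1x + fkx * r2x;
    W[1] += fiy * r1y + fky * r2y;
    W[2] += fiz * r1z + fkz * r2z;
  }
}

static BondTable make_bond_table(const IntegerMatrix& bonds,
                                 const NumericVector& bond_k,
                                 const NumericVector& bond_r0,
                                 const IntegerMatrix& angles,
                                 const NumericVector& angle_k,
                                 const NumericVector& angle_theta0) {
  BondTable bt;
  for (int b = 0; b < bonds.nrow(); ++b) {
    bt.bi.push_back(bonds(b, 0) - 1);
    bt.bj.push_back(bonds(b, 1) - 1);
    bt.bk.push_back(bond_k[b]);
    bt.br0.push_back(bond_r0[b]);
  }
  for (int t = 0; t < angles.nrow(); ++t) {
    bt.ai.push_back(angles(t, 0) - 1);
    bt.aj.push_back(angles(t, 1) - 1); // central
    bt.ak.push_back(angles(t, 2) - 1);
    bt.akang.push_back(angle_k[t]);
    bt.ath0.push_back(angle_theta0[t] * M_PI / 180.0);
  }
  return bt;
}

// [[Rcpp::export(name = ".cell_pairs_cpp")]]
IntegerMatrix cell_pairs_cpp(NumericMatrix pos, NumericVector box, double rc) {
  int n = pos.nrow();
  std::vector<double> px(n), py(n), pz(n);
  double bx[3] = {box[0], box[1], box[2]};
  for (int i = 0; i < n; ++i) { px[i] = pos(i,0); py[i] = pos(i,1); pz[i] = pos(i,2); }
  std::vector<int> pi, pj;
  // note: rc is folded in by scaling coordinates so the cell grid matches rc
  std::vector<double> sx(n), sy(n), sz(n);
  double sb[3] = {bx[0] / rc, bx[1] / rc, bx[2] / rc};
  for (int i = 0; i < n; ++i) { sx[i] = px[i] / rc; sy[i] = py[i] / rc; sz[i] = pz[i] / rc; }
  for_each_pair(sx, sy, sz, sb, 1.0, [&](int i, int j, double, double, double, double) {
    if (i < j) { pi.push_back(i + 1); pj.push_back(j + 1); }
    else { pi.push_back(j + 1); pj.push_back(i + 1); }
  });
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) { out(k, 0) = pi[k]; out(k, 1) = pj[k]; }
  return out;
}

// Conservative + bonded forces and per-axis virial (no thermostat terms).
// [[Rcpp::export(name = ".dpd_forces_cpp")]]
List dpd_forces_cpp(NumericMatrix pos, IntegerVector type, LogicalVector frozen,
                    NumericVector box, NumericMatrix a,
                    IntegerMatrix bonds, NumericVector bond_k, NumericVector bond_r0,
                    IntegerMatrix angles, NumericVector angle_k, NumericVector angle_theta0) {
  int n = pos.nrow();
  int ntypes = a.nrow();
  std::vector<double> px(n), py(n), pz(n), vx(n, 0.0), vy(n, 0.0), vz(n, 0.0);
  std::vector<int> ty(n);
  std::vector<char> fr(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i,0); py[i] = pos(i,1); pz[i] = pos(i,2);
    ty[i] = type[i] - 1; fr[i] = frozen[i] ? 1 : 0;
  }
  std::vector<double> amat(ntypes * ntypes);
  for (int i = 0; i < ntypes; ++i)
    for (int j = 0; j < ntypes; ++j) amat[i * ntypes + j] = a(i, j);
  double bx[3] = {box[0], box[1], box[2]};
  BondTable bt = make_bond_table(bonds, bond_k, bond_r0, angles, angle_k, angle_theta0);
  bt.build_adj(n);
  ForceEval fe;
  std::mt19937_64 rng(1);
  compute_forces(px, py, pz, vx, vy, vz, ty, fr, bx, amat.data(), ntypes,
                 0.0, 0.0, 1.0, bt, false, rng, fe);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) { F(i,0) = fe.fx[i]; F(i,1) = fe.fy[i]; F(i,2) = fe.fz[i]; }
  return List::create(_["force"] = F,
                      _["virial"] = NumericVector::create(fe.W[0], fe.W[1], fe.W[2]),
                      _["n_coincident"] = (double)fe.n_coincident);
}

// Modified velocity-Verlet DPD integration (Groot-Warren lambda scheme).
// Optional anisotropic Berendsen barostat on x and z; y is never rescaled.
// [[Rcpp::export(name = ".dpd_run_cpp")]]
List dpd_run_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
                 LogicalVector frozen, NumericVector box0, NumericMatrix a,
                 IntegerMatrix bonds, NumericVector bond_k, NumericVector bond_r0,
                 IntegerMatrix angles, NumericVector angle_k, NumericVector angle_theta0,
                 double dt, int n_steps, double lambda, double gamma, double sigma,
                 int seed,
                 bool barostat, double p_target, double tau_p, double kappa,
                 int sample_every, int log_every, double t0) {
  const int n = pos.nrow();
  const int ntypes = a.nrow();
  std::vector<double> px(n), py(n), pz(n), vx(n), vy(n), vz(n);
  std::vector<double> v0x(n), v0y(n), v0z(n);
  std::vector<int> ty(n);
  std::vector<char> fr(n);
  int n_mobile = 0;
  for (int i = 0; i < n; ++i) {
    px[i] = pos(i,0); py[i] = pos(i,1); pz[i] = pos(i,2);
    vx[i] = vel(i,0); vy[i] = vel(i,1); vz[i] = vel(i,2);
    ty[i] = type[i] - 1; fr[i] = frozen[i] ? 1 : 0;
    if (!fr[i]) ++n_mobile;
  }
  std::vector<double> amat(ntypes * ntypes);
  for (int i = 0; i < ntypes; ++i)
    for (int j = 0; j < ntypes; ++j) amat[i * ntypes + j] = a(i, j);
  double box[3] = {box0[0], box0[1], box0[2]};
  BondTable bt = make_bond_table(bonds, bond_k, bond_r0, angles, angle_k, angle_theta0);
  bt.build_adj(n);

  const double inv_sqrt_dt = 1.0 / std::sqrt(dt);
  std::mt19937_64 rng((uint64_t)seed);

  for (int i = 0; i < n; ++i) {
    px[i] = wrap01(px[i], box[0]);
    py[i] = wrap01(py[i], box[1]);
    pz[i] = wrap01(pz[i], box[2]);
  }

  ForceEval fe, fe_new;
  compute_forces(px, py, pz, vx, vy, vz, ty, fr, box, amat.data(), ntypes,
                 gamma, sigma, inv_sqrt_dt, bt, true, rng, fe);
  long n_coincident = fe.n_coincident;

  std::vector<List> frames;
  std::vector<double> log_time, log_T, log_Pxx, log_Pyy, log_Pzz,
      log_Lx, log_Ly, log_Lz, log_px, log_py, log_pz;

  auto kinetic = [&](double K[3]) {
    K[0] = K[1] = K[2] = 0.0;
    for (int i = 0; i < n; ++i) {
      if (fr[i]) continue;
      K[0] += vx[i] * vx[i]; K[1] += vy[i] * vy[i]; K[2] += vz[i] * vz[i];
    }
  };

  auto snapshot = [&](int step) {
    NumericMatrix P(n, 3), V(n, 3);
    for (int i = 0; i < n; ++i) {
      P(i,0) = px[i]; P(i,1) = py[i]; P(i,2) = pz[i];
      V(i,0) = vx[i]; V(i,1) = vy[i]; V(i,2) = vz[i];
    }
    frames.push_back(List::create(
      _["pos"] = P, _["vel"] = V,
      _["box"] = NumericVector::create(box[0], box[1], box[2]),
      _["time"] = t0 + step * dt, _["step"] = step));
  };

  auto log_state = [&](int step) {
    double K[3]; kinetic(K);
    double V = box[0] * box[1] * box[2];
    double T = n_mobile > 0 ? (K[0] + K[1] + K[2]) / (3.0 * n_mobile) : 0.0;
    double mx = 0, my = 0, mz = 0;
    for (int i = 0; i < n; ++i) {
      if (fr[i]) continue;
      mx += vx[i]; my += vy[i]; mz += vz[i];
    }
    log_time.push_back(t0 + step * dt);
    log_T.push_back(T);
    log_Pxx.push_back((K[0] + fe.W[0]) / V);
    log_Pyy.push_back((K[1] + fe.W[1]) / V);
    log_Pzz.push_back((K[2] + fe.W[2]) / V);
    log_Lx.push_back(box[0]); log_Ly.push_back(box[1]); log_Lz.push_back(box[2]);
    log_px.push_back(mx); log_py.push_back(my); log_pz.push_back(mz);
  };

  if (sample_every > 0 || n_steps == 0) snapshot(0);
  if (log_every > 0) log_state(0);

  for (int step = 1; step <= n_steps; ++step) {
    // position update + predicted velocity
    for (int i = 0; i < n; ++i) {
      if (fr[i]) continue;
      px[i] = wrap01(px[i] + dt * vx[i] + 0.5 * dt * dt * fe.fx[i], box[0]);
      py[i] = wrap01(py[i] + dt * vy[i] + 0.5 * dt * dt * fe.fy[i], box[1]);
      pz[i] = wrap01(pz[i] + dt * vz[i] + 0.5 * dt * dt * fe.fz[i], box[2]);
      v0x[i] = vx[i]; v0y[i] = vy[i]; v0z[i] = vz[i];
      vx[i] += lambda * dt * fe.fx[i];
      vy[i] += lambda * dt * fe.fy[i];
      vz[i] += lambda * dt * fe.fz[i];
    }
    compute_forces(px, py, pz, vx, vy, vz, ty, fr, box, amat.data(), ntypes,
                   gamma, sigma, inv_sqrt_dt, bt, true, rng, fe_new);
    n_coincident += fe_new.n_coincident;
    for (int i = 0; i < n; ++i) {
      if (fr[i]) continue;
      vx[i] = v0x[i] + 0.5 * dt * (fe.fx[i] + fe_new.fx[i]);
      vy[i] = v0y[i] + 0.5 * dt * (fe.fy[i] + fe_new.fy[i]);
      vz[i] = v0z[i] + 0.5 * dt * (fe.fz[i] + fe_new.fz[i]);
      if (!std::isfinite(px[i]) || !std::isfinite(vx[i]) ||
          !std::isfinite(py[i]) || !std::isfinite(vy[i]) ||
          !std::isfinite(pz[i]) || !std::isfinite(vz[i]))
        stop("non-finite coordinate or velocity at step %d, bead %d", step, i + 1);
    }
    fe.fx.swap(fe_new.fx); fe.fy.swap(fe_new.fy); fe.fz.swap(fe_new.fz);
    fe.W[0] = fe_new.W[0]; fe.W[1] = fe_new.W[1]; fe.W[2] = fe_new.W[2];

    if (barostat) {
      double K[3]; kinetic(K);
      double V = box[0] * box[1] * box[2];
      double Pxx = (K[0] + fe.W[0]) / V;
      double Pzz = (K[2] + fe.W[2]) / V;
      double mux = std::cbrt(1.0 - kappa * (dt / tau_p) * (p_target - Pxx));
      double muz = std::cbrt(1.0 - kappa * (dt / tau_p) * (p_target - Pzz));
      if (mux < 0.99) mux = 0.99; if (mux > 1.01) mux = 1.01;
      if (muz < 0.99) muz = 0.99; if (muz > 1.01) muz = 1.01;
      // frozen substrate translates rigidly with the scaled box center
      double cfx = 0.0, cfz = 0.0; int nf = 0;
      for (int i = 0; i < n; ++i) if (fr[i]) { cfx += px[i]; cfz += pz[i]; ++nf; }
      if (nf > 0) { cfx /= nf; cfz /= nf; }
      box[0] *= mux; box[2] *= muz;
      for (int i = 0; i < n; ++i) {
        if (fr[i]) {
          px[i] = wrap01(px[i] + (mux - 1.0) * cfx, box[0]);
          pz[i] = wrap01(pz[i] + (muz - 1.0) * cfz, box[2]);
        } else {
          px[i] = wrap01(px[i] * mux, box[0]);
          pz[i] = wrap01(pz[i] * muz, box[2]);
        }
      }
    }

    if (sample_every > 0 && (step % sample_every == 0)) snapshot(step);
    else if (step == n_steps) snapshot(step);
    if (log_every > 0 && (step % log_every == 0)) log_state(step);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  DataFrame log = DataFrame::create(
    _["time"] = log_time, _["temperature"] = log_T,
    _["Pxx"] = log_Pxx, _["Pyy"] = log_Pyy, _["Pzz"] = log_Pzz,
    _["Lx"] = log_Lx, _["Ly"] = log_Ly, _["Lz"] = log_Lz,
    _["px"] = log_px, _["py"] = log_py, _["pz"] = log_pz);

  return List::create(_["frames"] = wrap(frames), _["log"] = log,
                      _["n_coincident"] = (double)n_coincident,
                      _["box"] = NumericVector::create(box[0], box[1], box[2]));
}

// Random insertion of lipid molecules (rigid template copies) and water
// beads with a minimum inter-bead distance and a cylindrical exclusion
// matching the tube interior over its axial extent. Grid-accelerated.
// [[Rcpp::export(name = ".insert_beads_cpp")]]
List insert_beads_cpp(NumericMatrix fixed_pos, NumericVector box,
                      double excl_radius, double excl_halflen,
                      NumericVector excl_center,
                      NumericMatrix lipid_template, int n_lipids, int n_water,
                      double min_dist, int seed, int max_attempts) {
  const double bx = box[0], by = box[1], bz = box[2];
  const double cxc = excl_center[0], cyc = excl_center[1], czc = excl_center[2];
  const double md2 = min_dist * min_dist;

  int ncx = std::max(1, (int)std::floor(bx / min_dist));
  int ncy = std::max(1, (int)std::floor(by / min_dist));
  int ncz = std::max(1, (int)std::floor(bz / min_dist));
  // cap grid memory for large boxes
  ncx = std::min(ncx, 256); ncy = std::min(ncy, 256); ncz = std::min(ncz, 256);
  std::vector<std::vector<int>> grid(ncx * ncy * ncz);
  std::vector<double> gx, gy, gz;

  auto cell_of = [&](double x, double y, double z) {
    int cx = (int)(wrap01(x, bx) / bx * ncx); if (cx >= ncx) cx = ncx - 1;
    int cy = (int)(wrap01(y, by) / by * ncy); if (cy >= ncy) cy = ncy - 1;
    int cz = (int)(wrap01(z, bz) / bz * ncz); if (cz >= ncz) cz = ncz - 1;
    return (cx * ncy + cy) * ncz + cz;
  };
  auto add_bead = [&](double x, double y, double z) {
    gx.push_back(x); gy.push_back(y); gz.push_back(z);
    grid[cell_of(x, y, z)].push_back((int)gx.size() - 1);
  };
  auto too_close = [&](double x, double y, double z) {
    int cx = (int)(wrap01(x, bx) / bx * ncx); if (cx >= ncx) cx = ncx - 1;
    int cy = (int)(wrap01(y, by) / by * ncy); if (cy >= ncy) cy = ncy - 1;
    int cz = (int)(wrap01(z, bz) / bz * ncz); if (cz >= ncz) cz = ncz - 1;
    for (int ox = -1; ox <= 1; ++ox)
    for (int oy = -1; oy <= 1; ++oy)
    for (int oz = -1; oz <= 1; ++oz) {
      int c = (((cx + ox + ncx) % ncx) * ncy + ((cy + oy + ncy) % ncy)) * ncz +
              ((cz + oz + ncz) % ncz);
      for (int idx : grid[c]) {
        double dx = minimg(x - gx[idx], bx);
        double dy = minimg(y - gy[idx], by);
        double dz = minimg(z - gz[idx], bz);
        if (dx * dx + dy * dy + dz * dz < md2) return true;
      }
    }
    return false;
  };
  auto in_exclusion = [&](double x, double y, double z) {
    if (excl_radius <= 0.0) return false;
    double dy = minimg(y - cyc, by);
    if (std::fabs(dy) > excl_halflen) return false;
    double dx = minimg(x - cxc, bx);
    double dz = minimg(z - czc, bz);
    return dx * dx + dz * dz < excl_radius * excl_radius;
  };

  for (int i = 0; i < fixed_pos.nrow(); ++i)
    add_bead(fixed_pos(i, 0), fixed_pos(i, 1), fixed_pos(i, 2));

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> runif(0.0, 1.0);
  std::normal_distribution<double> gauss(0.0, 1.0);

  const int nlb = lipid_template.nrow();
  NumericMatrix lipid_out(n_lipids * nlb, 3);
  NumericMatrix water_out(n_water, 3);

  for (int m = 0; m < n_lipids; ++m) {
    bool placed = false;
    for (int att = 0; att < max_attempts && !placed; ++att) {
      // uniform random rotation via normalized quaternion
      double q0 = gauss(rng), q1 = gauss(rng), q2 = gauss(rng), q3 = gauss(rng);
      double qn = std::sqrt(q0*q0 + q1*q1 + q2*q2 + q3*q3);
      q0 /= qn; q1 /= qn; q2 /= qn; q3 /= qn;
      double R[3][3] = {
        {1 - 2*(q2*q2 + q3*q3), 2*(q1*q2 - q0*q3),     2*(q1*q3 + q0*q2)},
        {2*(q1*q2 + q0*q3),     1 - 2*(q1*q1 + q3*q3), 2*(q2*q3 - q0*q1)},
        {2*(q1*q3 - q0*q2),     2*(q2*q3 + q0*q1),     1 - 2*(q1*q1 + q2*q2)}
      };
      double ox = runif(rng) * bx, oy = runif(rng) * by, oz = runif(rng) * bz;
      std::vector<double> tx(nlb), tyy(nlb), tz(nlb);
      bool ok = true;
      for (int b = 0; b < nlb && ok; ++b) {
        double u = lipid_template(b, 0), v = lipid_template(b, 1), w = lipid_template(b, 2);
        double x = wrap01(ox + R[0][0]*u + R[0][1]*v + R[0][2]*w, bx);
        double y = wrap01(oy + R[1][0]*u + R[1][1]*v + R[1][2]*w, by);
        double z = wrap01(oz + R[2][0]*u + R[2][1]*v + R[2][2]*w, bz);
        if (in_exclusion(x, y, z) || too_close(x, y, z)) ok = false;
        tx[b] = x; tyy[b] = y; tz[b] = z;
      }
      if (ok) {
        for (int b = 0; b < nlb; ++b) {
          lipid_out(m * nlb + b, 0) = tx[b];
          lipid_out(m * nlb + b, 1) = tyy[b];
          lipid_out(m * nlb + b, 2) = tz[b];
          add_bead(tx[b], tyy[b], tz[b]);
        }
        placed = true;
      }
    }
    if (!placed)
      stop("failed to insert lipid %d of %d after %d attempts "
           "(box %.2f x %.2f x %.2f, min_dist %.2f): density infeasible",
           m + 1, n_lipids, max_attempts, bx, by, bz, min_dist);
  }

  for (int wv = 0; wv < n_water; ++wv) {
    bool placed = false;
    for (int att = 0; att < max_attempts && !placed; ++att) {
      double x = runif(rng) * bx, y = runif(rng) * by, z = runif(rng) * bz;
      if (in_exclusion(x, y, z) || too_close(x, y, z)) continue;
      water_out(wv, 0) = x; water_out(wv, 1) = y; water_out(wv, 2) = z;
      add_bead(x, y, z);
      placed = true;
    }
    if (!placed)
      stop("failed to insert water bead %d of %d after %d attempts "
           "(box %.2f x %.2f x %.2f, min_dist %.2f): density infeasible",
           wv + 1, n_water, max_attempts, bx, by, bz, min_dist);
  }

  return List::create(_["lipid_pos"] = lipid_out, _["water_pos"] = water_out);
}
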
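// DPD engine: soft pair forces with pairwise thermostat, harmonic bonds,
// angle bending, constant per-bead pulling, anchored beads, modified
// velocity-Verlet integration under full periodic boundaries.
//
// Randomness is counter-based: the Gaussian variate of a pair (i,j) at force
// evaluation `ctr` is a pure function of (seed, ctr, min(i,j), max(i,j)), so
// trajectories are bitwise reproducible regardless of evaluation order or of
// how a run is partitioned into calls.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const double DEGEN_R = 1e-9; // below this, beads count as coincident

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t pair_key(uint64_t seed, uint64_t ctr, int i, int j) {
  if (i > j) std::swap(i, j);
  uint64_t h = splitmix64(seed ^ 0x8C2F9D1540CB24B5ULL);
  h = splitmix64(h ^ ctr);
  h = splitmix64(h ^ (((uint64_t)(uint32_t)i << 32) | (uint32_t)j));
  return h;
}

// one standard Gaussian from a 64-bit key (Box-Muller, cosine branch)
static inline double key_gauss(uint64_t h) {
  double u1 = ((double)(h >> 32) + 1.0) * (1.0 / 4294967296.0); // (0,1]
  double u2 = (double)(h & 0xFFFFFFFFULL) * (1.0 / 4294967296.0);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

// deterministic unit vector for degenerate (coincident) contacts
static inline void key_unit_vector(uint64_t h, double *e) {
  double n2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    h = splitmix64(h);
    e[k] = key_gauss(h);
    n2 += e[k] * e[k];
  }
  if (n2 < 1e-300) { e[0] = 1.0; e[1] = 0.0; e[2] = 0.0; n2 = 1.0; }
  double inv = 1.0 / std::sqrt(n2);
  for (int k = 0; k < 3; ++k) e[k] *= inv;
}

static inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

struct PairParams {
  const double *a;      // ntype x ntype, column-major
  int ntype;
  double gamma, sigma, rcut, inv_sqrt_dt;
  uint64_t seed, ctr;
};

// accumulate the DPD pair force of (i,j) separated by dx (min-image applied)
static inline void pair_kernel(int i, int j, const double *dx,
                               const double *vel, int n, const int *type,
                               const PairParams &pp, double *F) {
  double r2 = dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2];
  if (r2 >= pp.rcut * pp.rcut) return;
  double aij = pp.a[type[i] + pp.ntype * type[j]];
  double r = std::sqrt(r2);
  if (r < DEGEN_R) {
    // soft potentials make exact overlaps legal: push apart with the full
    // conservative amplitude along a deterministic direction; no thermostat
    double e[3];
    key_unit_vector(pair_key(pp.seed, pp.ctr, i, j) ^ 0xA5A5A5A5A5A5A5A5ULL, e);
    for (int k = 0; k < 3; ++k) {
      F[i + k * n] += aij * e[k];
      F[j + k * n] -= aij * e[k];
    }
    return;
  }
  double w = 1.0 - r / pp.rcut;
  double ex = dx[0] / r, ey = dx[1] / r, ez = dx[2] / r;
  double dvx = vel[i] - vel[j];
  double dvy = vel[i + n] - vel[j + n];
  double dvz = vel[i + 2 * n] - vel[j + 2 * n];
  double rv = ex * dvx + ey * dvy + ez * dvz;
  double zeta = key_gauss(pair_key(pp.seed, pp.ctr, i, j));
  double f = aij * w - pp.gamma * w * w * rv +
             pp.sigma * w * zeta * pp.inv_sqrt_dt;
  F[i] += f * ex;          F[j] -= f * ex;
  F[i + n] += f * ey;      F[j + n] -= f * ey;
  F[i + 2 * n] += f * ez;  F[j + 2 * n] -= f * ez;
}

static void pair_forces_all_pairs(const double *pos, const double *vel, int n,
                                  const int *type, const double *box,
                                  const PairParams &pp, double *F) {
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx[3];
      for (int k = 0; k < 3; ++k)
        dx[k] = min_image(pos[i + k * n] - pos[j + k * n], box[k]);
      pair_kernel(i, j, dx, vel, n, type, pp, F);
    }
}

// Cell list over the periodic box; cell edge >= rcut; half stencil + self.
// Beads are gathered into cell-sorted contiguous buffers and the periodic
// shift of each neighbour cell is applied once per cell pair, so the inner
// loop is branch- and division-free until the cutoff test passes.
static void pair_forces_cell_list(const double *pos, const double *vel, int n,
                                  const int *type, const double *box,
                                  const PairParams &pp, double *F) {
  int nc[3];
  for (int k = 0; k < 3; ++k) {
    nc[k] = (int)std::floor(box[k] / pp.rcut);
    if (nc[k] < 1) nc[k] = 1;
  }
  if (nc[0] < 3 || nc[1] < 3 || nc[2] < 3) {
    // too few cells for a non-duplicating stencil: fall back
    pair_forces_all_pairs(pos, vel, n, type, box, pp, F);
    return;
  }
  int ncells = nc[0] * nc[1] * nc[2];
  std::vector<int> count(ncells + 1, 0), cell_of(n);
  for (int i = 0; i < n; ++i) {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      int ci = (int)std::floor(pos[i + k * n] / box[k] * nc[k]);
      ci %= nc[k];
      if (ci < 0) ci += nc[k];
      c[k] = ci;
    }
    cell_of[i] = c[0] + nc[0] * (c[1] + nc[1] * c[2]);
    ++count[cell_of[i] + 1];
  }
  for (int c = 0; c < ncells; ++c) count[c + 1] += count[c];
  // gather into cell-sorted SoA buffers
  std::vector<int> start(count.begin(), count.end() - 1);
  std::vector<double> sp(3 * n), sv(3 * n), sf(3 * n, 0.0);
  std::vector<int> sid(n), sty(n);
  {
    std::vector<int> cursor(start);
    for (int i = 0; i < n; ++i) {
      int s = cursor[cell_of[i]]++;
      sid[s] = i; sty[s] = type[i];
      for (int k = 0; k < 3; ++k) {
        sp[3 * s + k] = pos[i + k * n];
        sv[3 * s + k] = vel[i + k * n];
      }
    }
  }
  const double rc2 = pp.rcut * pp.rcut;
  static const int off[13][3] = {
    {1, 0, 0}, {-1, 1, 0}, {0, 1, 0}, {1, 1, 0},
    {-1, -1, 1}, {0, -1, 1}, {1, -1, 1},
    {-1, 0, 1}, {0, 0, 1}, {1, 0, 1},
    {-1, 1, 1}, {0, 1, 1}, {1, 1, 1}};
  // process one (i-bead, j-cell slice) pair with a constant shift
  auto slice = [&](int i, int j0, int j1, double shx, double shy,
                   double shz) {
    double xi = sp[3 * i] + shx, yi = sp[3 * i + 1] + shy,
           zi = sp[3 * i + 2] + shz;
    double fx = 0, fy = 0, fz = 0;
    for (int j = j0; j < j1; ++j) {
      double dx = xi - sp[3 * j], dy = yi - sp[3 * j + 1],
             dz = zi - sp[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      double aij = pp.a[sty[i] + pp.ntype * sty[j]];
      double r = std::sqrt(r2);
      int gi = sid[i], gj = sid[j];
      if (r < DEGEN_R) {
        double e[3];
        key_unit_vector(pair_key(pp.seed, pp.ctr, gi, gj) ^
                        0xA5A5A5A5A5A5A5A5ULL, e);
        fx += aij * e[0]; fy += aij * e[1]; fz += aij * e[2];
        sf[3 * j] -= aij * e[0]; sf[3 * j + 1] -= aij * e[1];
        sf[3 * j + 2] -= aij * e[2];
        continue;
      }
      double inv_r = 1.0 / r;
      double w = 1.0 - r / pp.rcut;
      double ex = dx * inv_r, ey = dy * inv_r, ez = dz * inv_r;
      double rv = ex * (sv[3 * i] - sv[3 * j]) +
                  ey * (sv[3 * i + 1] - sv[3 * j + 1]) +
                  ez * (sv[3 * i + 2] - sv[3 * j + 2]);
      double zeta = key_gauss(pair_key(pp.seed, pp.ctr, gi, gj));
      double f = aij * w - pp.gamma * w * w * rv +
                 pp.sigma * w * zeta * pp.inv_sqrt_dt;
      fx += f * ex; fy += f * ey; fz += f * ez;
      sf[3 * j] -= f * ex; sf[3 * j + 1] -= f * ey; sf[3 * j + 2] -= f * ez;
    }
    sf[3 * i] += fx; sf[3 * i + 1] += fy; sf[3 * i + 2] += fz;
  };
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int cell = cx + nc[0] * (cy + nc[1] * cz);
        int i0 = start[cell], i1 = count[cell + 1];
        for (int i = i0; i < i1; ++i)
          slice(i, i + 1, i1, 0.0, 0.0, 0.0);
        for (int m = 0; m < 13; ++m) {
          int rx = cx + off[m][0], ry = cy + off[m][1], rz = cz + off[m][2];
          double shx = 0, shy = 0, shz = 0;
          if (rx < 0) { rx += nc[0]; shx = -box[0]; }
          else if (rx >= nc[0]) { rx -= nc[0]; shx = box[0]; }
          if (ry < 0) { ry += nc[1]; shy = -box[1]; }
          else if (ry >= nc[1]) { ry -= nc[1]; shy = box[1]; }
          if (rz < 0) { rz += nc[2]; shz = -box[2]; }
          else if (rz >= nc[2]) { rz -= nc[2]; shz = box[2]; }
          int other = rx + nc[0] * (ry + nc[1] * rz);
          int j0 = start[other], j1 = count[other + 1];
          if (j0 == j1) continue;
          // shift i into the neighbour cell's frame: dx = (xi - sh') - xj
          // with sh' chosen so i sees j's nearest image
          for (int i = i0; i < i1; ++i)
            slice(i, j0, j1, -shx, -shy, -shz);
        }
      }
  // scatter back to original ordering
  for (int s = 0; s < n; ++s) {
    int i = sid[s];
    F[i] += sf[3 * s];
    F[i + n] += sf[3 * s + 1];
    F[i + 2 * n] += sf[3 * s + 2];
  }
}

static void bond_forces_impl(const double *pos, int n, const double *box,
                             const int *bi, const int *bj, const double *ks,
                             const double *rs, int nb, double *F) {
  for (int b = 0; b < nb; ++b) {
    int i = bi[b], j = bj[b];
    double dx[3];
    for (int k = 0; k < 3; ++k)
      dx[k] = min_image(pos[i + k * n] - pos[j + k * n], box[k]);
    double r = std::sqrt(dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2]);
    if (r < DEGEN_R) {
      double e[3];
      key_unit_vector(pair_key(0x0B0DULL, 0, i, j), e);
      for (int k = 0; k < 3; ++k) {
        F[i + k * n] += ks[b] * e[k];
        F[j + k * n] -= ks[b] * e[k];
      }
      continue;
    }
    double f = ks[b] * (1.0 - r / rs[b]) / r; // along dx
    for (int k = 0; k < 3; ++k) {
      F[i + k * n] += f * dx[k];
      F[j + k * n] -= f * dx[k];
    }
  }
}

static void angle_forces_impl(const double *pos, int n, const double *box,
                              const int *ai, const int *aj, const int *ak,
                              const double *kt, const double *t0, int na,
                              double *F) {
  const double eps = 1e-12;
  for (int t = 0; t < na; ++t) {
    int i = ai[t], j = aj[t], k = ak[t];
    double u[3], v[3];
    for (int d = 0; d < 3; ++d) {
      u[d] = min_image(pos[i + d * n] - pos[j + d * n], box[d]);
      v[d] = min_image(pos[k + d * n] - pos[j + d * n], box[d]);
    }
    double lu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    double lv = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    if (lu < DEGEN_R || lv < DEGEN_R) continue;
    double c = (u[0] * v[0] + u[1] * v[1] + u[2] * v[2]) / (lu * lv);
    if (c > 1.0 - eps) c = 1.0 - eps;
    if (c < -1.0 + eps) c = -1.0 + eps;
    double s = std::sqrt(1.0 - c * c);
    double theta = std::acos(c);
    // U = kt (theta - t0)^2 ; dU/dcos = -2 kt (theta - t0) / sin(theta)
    double coef = 2.0 * kt[t] * (theta - t0[t]) / s;
    for (int d = 0; d < 3; ++d) {
      double fi = coef * (v[d] / lv - c * u[d] / lu) / lu;
      double fk = coef * (u[d] / lu - c * v[d] / lv) / lv;
      F[i + d * n] += fi;
      F[k + d * n] += fk;
      F[j + d * n] -= fi + fk;
    }
  }
}

struct SystemView {
  const int *type;
  const int *anchored; // logical
  const double *a;
  int ntype, n;
  double gamma, sigma, rcut;
  const double *box;
  const int *bi, *bj; const double *bks, *brs; int nb;
  const int *ai, *aj, *ak; const double *akt, *at0; int na;
  const double *pull; const int *ptar; int npt;
};

static void total_forces(const SystemView &S, const double *pos,
                         const double *vel, double dt, uint64_t seed,
                         uint64_t ctr, bool cell_list, double *F) {
  std::fill(F, F + 3 * S.n, 0.0);
  PairParams pp;
  pp.a = S.a; pp.ntype = S.ntype;
  pp.gamma = S.gamma; pp.sigma = S.sigma; pp.rcut = S.rcut;
  pp.inv_sqrt_dt = 1.0 / std::sqrt(dt);
  pp.seed = seed; pp.ctr = ctr;
  if (cell_list)
    pair_forces_cell_list(pos, vel, S.n, S.type, S.box, pp, F);
  else
    pair_forces_all_pairs(pos, vel, S.n, S.type, S.box, pp, F);
  bond_forces_impl(pos, S.n, S.box, S.bi, S.bj, S.bks, S.brs, S.nb, F);
  angle_forces_impl(pos, S.n, S.box, S.ai, S.aj, S.ak, S.akt, S.at0, S.na, F);
  for (int m = 0; m < S.npt; ++m) {
    int i = S.ptar[m];
    F[i] += S.pull[0];
    F[i + S.n] += S.pull[1];
    F[i + 2 * S.n] += S.pull[2];
  }
  // anchored beads: forces computed (they push neighbours) then zeroed
  for (int i = 0; i < S.n; ++i)
    if (S.anchored[i]) { F[i] = 0.0; F[i + S.n] = 0.0; F[i + 2 * S.n] = 0.0; }
}

static SystemView make_view(const IntegerVector &type,
                            const IntegerVector &anchored,
                            const NumericMatrix &a, double gamma, double sigma,
                            double rcut, const NumericVector &box,
                            const IntegerMatrix &bonds,
                            const NumericVector &bks, const NumericVector &brs,
                            const IntegerMatrix &angles,
                            const NumericVector &akt, const NumericVector &at0,
                            const NumericVector &pull,
                            const IntegerVector &ptar) {
  SystemView S;
  S.type = type.begin(); S.anchored = anchored.begin();
  S.a = a.begin(); S.ntype = a.nrow(); S.n = type.size();
  S.gamma = gamma; S.sigma = sigma; S.rcut = rcut; S.box = box.begin();
  S.nb = bonds.nrow();
  S.bi = S.nb ? &bonds(0, 0) : NULL;
  S.bj = S.nb ? &bonds(0, 1) : NULL;
  S.bks = bks.begin(); S.brs = brs.begin();
  S.na = angles.nrow();
  S.ai = S.na ? &angles(0, 0) : NULL;
  S.aj = S.na ? &angles(0, 1) : NULL;
  S.ak = S.na ? &angles(0, 2) : NULL;
  S.akt = akt.begin(); S.at0 = at0.begin();
  S.pull = pull.begin(); S.ptar = ptar.begin(); S.npt = ptar.size();
  return S;
}

// [[Rcpp::export]]
NumericMatrix pair_forces_cpp(NumericMatrix pos, NumericMatrix vel,
                              IntegerVector type, NumericMatrix a,
                              double gamma, double sigma, double rcut,
                              NumericVector box, double dt, double seed,
                              double counter, bool cell_list) {
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  PairParams pp;
  pp.a = a.begin(); pp.ntype = a.nrow();
  pp.gamma = gamma; pp.sigma = sigma; pp.rcut = rcut;
  pp.inv_sqrt_dt = 1.0 / std::sqrt(dt);
  pp.seed = (uint64_t)seed; pp.ctr = (uint64_t)counter;
  if (cell_list)
    pair_forces_cell_list(pos.begin(), vel.begin(), n, type.begin(),
                          box.begin(), pp, F.begin());
  else
    pair_forces_all_pairs(pos.begin(), vel.begin(), n, type.begin(),
                          box.begin(), pp, F.begin());
  return F;
}

// [[Rcpp::export]]
NumericMatrix bond_forces_cpp(NumericMatrix pos, NumericVector box,
                              IntegerMatrix bonds, NumericVector ks,
                              NumericVector rs) {
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  if (bonds.nrow())
    bond_forces_impl(pos.begin(), n, box.begin(), &bonds(0, 0), &bonds(0, 1),
                     ks.begin(), rs.begin(), bonds.nrow(), F.begin());
  return F;
}

// [[Rcpp::export]]
NumericMatrix angle_forces_cpp(NumericMatrix pos, NumericVector box,
                               IntegerMatrix angles, NumericVector kt,
                               NumericVector t0) {
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  if (angles.nrow())
    angle_forces_impl(pos.begin(), n, box.begin(), &angles(0, 0),
                      &angles(0, 1), &angles(0, 2), kt.begin(), t0.begin(),
                      angles.nrow(), F.begin());
  return F;
}

// [[Rcpp::export]]
List dpd_run_cpp(NumericMatrix pos, NumericMatrix vel,
                 Nullable<NumericMatrix> forces, IntegerVector type,
                 IntegerVector anchored, NumericMatrix a, double gamma,
                 double sigma, double rcut, NumericVector box,
                 IntegerMatrix bonds, NumericVector bks, NumericVector brs,
                 IntegerMatrix angles, NumericVector akt, NumericVector at0,
                 NumericVector pull, IntegerVector pull_targets, double dt,
                 double lambda, double seed, double step0, int nsteps,
                 bool cell_list) {
  int n = pos.nrow();
  NumericMatrix P = clone(pos), V = clone(vel);
  SystemView S = make_view(type, anchored, a, gamma, sigma, rcut, box, bonds,
                           bks, brs, angles, akt, at0, pull, pull_targets);
  uint64_t useed = (uint64_t)seed;
  uint64_t step = (uint64_t)step0;
  std::vector<double> F(3 * n), Fnew(3 * n), Vt(3 * n);
  if (forces.isNotNull()) {
    NumericMatrix F0(forces);
    std::copy(F0.begin(), F0.end(), F.begin());
  } else {
    total_forces(S, P.begin(), V.begin(), dt, useed, step, cell_list,
                 F.data());
  }
  double *p = P.begin(), *v = V.begin();
  for (int s = 0; s < nsteps; ++s) {
    // position update + velocity prediction (skip anchored beads)
    for (int i = 0; i < n; ++i) {
      if (anchored[i]) continue;
      for (int d = 0; d < 3; ++d) {
        int idx = i + d * n;
        p[idx] += dt * v[idx] + 0.5 * dt * dt * F[idx];
        // wrap into [0, L)
        p[idx] -= box[d] * std::floor(p[idx] / box[d]);
        Vt[idx] = v[idx] + lambda * dt * F[idx];
      }
      if (!std::isfinite(p[i]) || !std::isfinite(p[i + n]) ||
          !std::isfinite(p[i + 2 * n]))
        stop("non-finite coordinate for bead %d at step %d", i + 1,
             (int)(step + 1));
    }
    for (int i = 0; i < n; ++i)
      if (anchored[i])
        for (int d = 0; d < 3; ++d) Vt[i + d * n] = 0.0;
    ++step;
    total_forces(S, p, Vt.data(), dt, useed, step, cell_list, Fnew.data());
    // velocity correction
    for (int i = 0; i < n; ++i) {
      if (anchored[i]) continue;
      for (int d = 0; d < 3; ++d) {
        int idx = i + d * n;
        v[idx] += 0.5 * dt * (F[idx] + Fnew[idx]);
      }
    }
    std::swap(F, Fnew);
  }
  NumericMatrix Fout(n, 3);
  std::copy(F.begin(), F.end(), Fout.begin());
  return List::create(_["positions"] = P, _["velocities"] = V,
                      _["forces"] = Fout, _["step"] = (double)step);
}
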
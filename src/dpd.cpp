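// Core DPD kernels: pair forces with per-species cutoffs, bonded terms,
// Slater-smeared Ewald electrostatics, Groot-Warren integrator and
// Lees-Edwards sheared boundaries.
//
// Random numbers for the pair thermostat come from a counter-based stream
// keyed on (seed, step, sorted pair ids), so zeta_ij == zeta_ji and the
// brute-force and cell-list pair traversals see identical noise.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t h) {
  // strictly inside (0,1)
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// inverse normal CDF (Beasley-Springer-Moro), |error| < 3e-9
static inline double inv_norm_cdf(double u) {
  static const double a[4] = {2.50662823884, -18.61500062529,
                              41.39119773534, -25.44106049637};
  static const double b[4] = {-8.47351093090, 23.08336743743,
                              -21.06224101826, 3.13082909833};
  static const double c[9] = {0.3374754822726147, 0.9761690190917186,
                              0.1607979714918209, 0.0276438810333863,
                              0.0038405729373609, 0.0003951896511919,
                              0.0000321767881768, 0.0000002888167364,
                              0.0000003960315187};
  double y = u - 0.5;
  if (std::fabs(y) < 0.42) {
    double r = y * y;
    return y * (((a[3] * r + a[2]) * r + a[1]) * r + a[0]) /
           ((((b[3] * r + b[2]) * r + b[1]) * r + b[0]) * r + 1.0);
  }
  double r = (y > 0) ? 1.0 - u : u;
  r = std::log(-std::log(r));
  double x = c[0] + r * (c[1] + r * (c[2] + r * (c[3] + r * (c[4] +
             r * (c[5] + r * (c[6] + r * (c[7] + r * c[8])))))));
  return (y < 0) ? -x : x;
}

// one standard normal per (seed, step, i<j, salt)
static inline double pair_gauss(uint64_t seed, uint64_t step,
                                uint64_t i, uint64_t j, uint64_t salt) {
  uint64_t k = splitmix64(seed ^ splitmix64(step + 0x1234ULL));
  k = splitmix64(k ^ ((i << 32) | (j + 1ULL)) ^ (salt << 17));
  return inv_norm_cdf(u01(k));
}

// --------------------------------------------------------------- helpers ---

struct MinImg {
  double L, shear_offset, shear_dv; // shear_dv = shear_rate * L
};

// minimum-image separation, Lees-Edwards aware (shear: flow x, gradient z).
// Coordinates are wrapped into [0, L), so each component needs at most one
// box shift; the z crossing drags the x image by the accumulated offset.
// Returns the z image count so the caller can correct the image velocity.
static inline int min_image_pos(const MinImg& mi, double& dx, double& dy,
                                double& dz) {
  const double h = 0.5 * mi.L;
  int nz = 0;
  if (dz > h) {
    dz -= mi.L; dx -= mi.shear_offset; nz = 1;
  } else if (dz < -h) {
    dz += mi.L; dx += mi.shear_offset; nz = -1;
  }
  if (dx > h) { dx -= mi.L; if (dx > h) dx -= mi.L; }
  else if (dx < -h) { dx += mi.L; if (dx < -h) dx += mi.L; }
  if (dy > h) dy -= mi.L; else if (dy < -h) dy += mi.L;
  return nz;
}

static inline void min_image(const MinImg& mi, double& dx, double& dy,
                             double& dz, double& dvx) {
  dvx -= min_image_pos(mi, dx, dy, dz) * mi.shear_dv;
}

struct FFParams {
  int nspec;
  std::vector<double> aij, Rij, Rij2, invRij; // nspec x nspec, row-major
  double sigma, gamma, dt, inv_sqrt_dt;
  double max_cut;
};

struct ElectroParams {
  bool enabled = false;
  double coupling = 0.0;     // Gamma
  double beta = 0.929;       // Slater smearing
  double alpha = 0.0;        // Ewald splitting
  double rcut = 3.0;         // real-space cutoff
  int kmax = 0;              // reciprocal extent
};

struct System {
  int N;
  std::vector<double> x, y, z, vx, vy, vz;
  std::vector<int> spec;           // 0-based
  std::vector<double> q;
  double L;
  double shear_offset, shear_rate;
};

struct Bonded {
  std::vector<int> bi, bj;          // 0-based bonds
  std::vector<double> l0, C;
  std::vector<int> ai, aj, ak;      // angles, aj central
  std::vector<double> th0, D;
};

struct Forces {
  std::vector<double> fx, fy, fz;
  // optional breakdown
  bool keep_parts = false;
  std::vector<double> cx, cy, cz, dx_, dy_, dz_, rx, ry, rz,
      bx, by, bz, ax_, ay_, az_, ex, ey, ez;
  double e_elec = 0.0;
  void init(int N, bool parts) {
    keep_parts = parts;
    fx.assign(N, 0.0); fy.assign(N, 0.0); fz.assign(N, 0.0);
    if (parts) {
      cx.assign(N, 0.0); cy.assign(N, 0.0); cz.assign(N, 0.0);
      dx_.assign(N, 0.0); dy_.assign(N, 0.0); dz_.assign(N, 0.0);
      rx.assign(N, 0.0); ry.assign(N, 0.0); rz.assign(N, 0.0);
      bx.assign(N, 0.0); by.assign(N, 0.0); bz.assign(N, 0.0);
      ax_.assign(N, 0.0); ay_.assign(N, 0.0); az_.assign(N, 0.0);
      ex.assign(N, 0.0); ey.assign(N, 0.0); ez.assign(N, 0.0);
    }
    e_elec = 0.0;
  }
};

// non-bonded DPD interaction for one pair
static inline void pair_dpd(const System& S, const FFParams& ff,
                            const MinImg& mi, Forces& F,
                            uint64_t seed, uint64_t step,
                            int i, int j) {
  double dx = S.x[i] - S.x[j];
  double dy = S.y[i] - S.y[j];
  double dz = S.z[i] - S.z[j];
  int nz = min_image_pos(mi, dx, dy, dz);
  int a = S.spec[i], b = S.spec[j];
  int ab = a * ff.nspec + b;
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= ff.Rij2[ab]) return;
  double dvx = S.vx[i] - S.vx[j] - nz * mi.shear_dv;
  double dvy = S.vy[i] - S.vy[j];
  double dvz = S.vz[i] - S.vz[j];
  double aij = ff.aij[ab];
  uint64_t pi = (uint64_t)std::min(i, j), pj = (uint64_t)std::max(i, j);
  double inv_r = 1.0 / std::sqrt(r2);
  double r = r2 * inv_r;
  double ux, uy, uz;
  if (r < 1e-12) {
    // coincident beads: seeded random direction, maximum repulsion
    double gx = pair_gauss(seed, step, pi, pj, 11);
    double gy = pair_gauss(seed, step, pi, pj, 12);
    double gz = pair_gauss(seed, step, pi, pj, 13);
    double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
    if (gn < 1e-12) { gx = 1.0; gy = 0.0; gz = 0.0; gn = 1.0; }
    double fmag = aij;
    double fx = fmag * gx / gn, fy = fmag * gy / gn, fz = fmag * gz / gn;
    F.fx[i] += fx; F.fy[i] += fy; F.fz[i] += fz;
    F.fx[j] -= fx; F.fy[j] -= fy; F.fz[j] -= fz;
    if (F.keep_parts) {
      F.cx[i] += fx; F.cy[i] += fy; F.cz[i] += fz;
      F.cx[j] -= fx; F.cy[j] -= fy; F.cz[j] -= fz;
    }
    return;
  }
  ux = dx * inv_r; uy = dy * inv_r; uz = dz * inv_r;
  double w = 1.0 - r * ff.invRij[ab];   // omega^R
  double fc = aij * w;                  // conservative magnitude
  double rdotv = ux * dvx + uy * dvy + uz * dvz;
  double fd = -ff.gamma * w * w * rdotv; // dissipative (omega^D = w^2)
  double zeta = pair_gauss(seed, step, pi, pj, 0);
  double fr = ff.sigma * w * zeta * ff.inv_sqrt_dt;
  double fm = fc + fd + fr;
  F.fx[i] += fm * ux; F.fy[i] += fm * uy; F.fz[i] += fm * uz;
  F.fx[j] -= fm * ux; F.fy[j] -= fm * uy; F.fz[j] -= fm * uz;
  if (F.keep_parts) {
    F.cx[i] += fc * ux; F.cy[i] += fc * uy; F.cz[i] += fc * uz;
    F.cx[j] -= fc * ux; F.cy[j] -= fc * uy; F.cz[j] -= fc * uz;
    F.dx_[i] += fd * ux; F.dy_[i] += fd * uy; F.dz_[i] += fd * uz;
    F.dx_[j] -= fd * ux; F.dy_[j] -= fd * uy; F.dz_[j] -= fd * uz;
    F.rx[i] += fr * ux; F.ry[i] += fr * uy; F.rz[i] += fr * uz;
    F.rx[j] -= fr * ux; F.ry[j] -= fr * uy; F.rz[j] -= fr * uz;
  }
}

// ------------------------------------------------------------ cell lists ---

struct CellList {
  int nc;                 // cells per dimension
  double w;               // cell width
  std::vector<int> head, next;
  void build(const System& S, double cut) {
    nc = std::max(1, (int)std::floor(S.L / cut));
    w = S.L / nc;
    head.assign(nc * nc * nc, -1);
    next.assign(S.N, -1);
    for (int i = 0; i < S.N; ++i) {
      int cx = (int)std::floor(S.x[i] / w) % nc; if (cx < 0) cx += nc;
      int cy = (int)std::floor(S.y[i] / w) % nc; if (cy < 0) cy += nc;
      int cz = (int)std::floor(S.z[i] / w) % nc; if (cz < 0) cz += nc;
      int c = (cz * nc + cy) * nc + cx;
      next[i] = head[c];
      head[c] = i;
    }
  }
};

// visit all pairs within `cut` (callback by template) -- used for both DPD
// short-range and real-space electrostatics
template <typename PairFn>
static void for_pairs(const System& S, double cut, bool use_cells,
                      bool sheared, PairFn fn) {
  if (!use_cells || S.L < 3.0 * cut) {
    for (int i = 0; i < S.N; ++i)
      for (int j = i + 1; j < S.N; ++j) fn(i, j);
    return;
  }
  CellList cl;
  cl.build(S, cut);
  int nc = cl.nc;
  // half list of neighbour offsets (13) + self
  static const int off[13][3] = {
      {1, 0, 0}, {0, 1, 0}, {1, 1, 0}, {-1, 1, 0},
      {0, 0, 1}, {1, 0, 1}, {-1, 0, 1}, {0, 1, 1},
      {0, -1, 1}, {1, 1, 1}, {-1, 1, 1}, {1, -1, 1}, {-1, -1, 1}};
  for (int cz = 0; cz < nc; ++cz)
    for (int cy = 0; cy < nc; ++cy)
      for (int cx = 0; cx < nc; ++cx) {
        int c = (cz * nc + cy) * nc + cx;
        // within-cell pairs
        for (int i = cl.head[c]; i >= 0; i = cl.next[i])
          for (int j = cl.next[i]; j >= 0; j = cl.next[j]) fn(i, j);
        // neighbour cells
        for (int o = 0; o < 13; ++o) {
          int nz = cz + off[o][2];
          bool crossz = (nz >= nc || nz < 0);
          if (sheared && crossz) continue; // handled below
          int nx = (cx + off[o][0] + nc) % nc;
          int ny = (cy + off[o][1] + nc) % nc;
          int nzz = (nz + nc) % nc;
          int c2 = (nzz * nc + ny) * nc + nx;
          for (int i = cl.head[c]; i >= 0; i = cl.next[i])
            for (int j = cl.head[c2]; j >= 0; j = cl.next[j]) fn(i, j);
        }
        // sheared z-boundary: image cells are displaced in x by the
        // accumulated offset, so scan the whole x-row of the wrapped layer
        if (sheared && cz == nc - 1) {
          for (int dy = -1; dy <= 1; ++dy) {
            int ny = (cy + dy + nc) % nc;
            for (int nx = 0; nx < nc; ++nx) {
              int c2 = (0 * nc + ny) * nc + nx;
              for (int i = cl.head[c]; i >= 0; i = cl.next[i])
                for (int j = cl.head[c2]; j >= 0; j = cl.next[j]) {
                  if (c2 == c && j <= i) continue;
                  fn(i, j);
                }
            }
          }
        }
      }
}

// Verlet neighbour list with skin, used by the integration loop
struct NeighList {
  std::vector<int> pi, pj;
  std::vector<double> x0, y0, z0;
  double cut = 0.0;  // list cutoff = force cutoff + skin
  double so0 = 0.0;  // shear offset at build time
  void build(const System& S, double c) {
    cut = c;
    pi.clear(); pj.clear();
    MinImg mi{S.L, S.shear_offset, S.shear_rate * S.L};
    double c2 = c * c;
    for_pairs(S, c, true, S.shear_offset != 0.0, [&](int i, int j) {
      double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j],
             dz = S.z[i] - S.z[j], dvx = 0.0;
      min_image(mi, dx, dy, dz, dvx);
      if (dx * dx + dy * dy + dz * dz < c2) {
        pi.push_back(i);
        pj.push_back(j);
      }
    });
    // canonical pair order: keeps force accumulation bitwise independent
    // of when the list was last rebuilt (restart == uninterrupted run)
    std::vector<uint64_t> keys(pi.size());
    for (size_t k = 0; k < pi.size(); ++k) {
      uint64_t a = (uint64_t)std::min(pi[k], pj[k]);
      uint64_t b = (uint64_t)std::max(pi[k], pj[k]);
      keys[k] = (a << 32) | b;
    }
    std::sort(keys.begin(), keys.end());
    for (size_t k = 0; k < keys.size(); ++k) {
      pi[k] = (int)(keys[k] >> 32);
      pj[k] = (int)(keys[k] & 0xFFFFFFFFULL);
    }
    x0 = S.x; y0 = S.y; z0 = S.z;
    so0 = S.shear_offset;
  }
  double max_disp2(const System& S) const {
    double m = 0.0;
    MinImg mi{S.L, S.shear_offset, S.shear_rate * S.L};
    for (int i = 0; i < S.N; ++i) {
      double dx = S.x[i] - x0[i], dy = S.y[i] - y0[i], dz = S.z[i] - z0[i],
             dvx = 0.0;
      min_image(mi, dx, dy, dz, dvx);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > m) m = d2;
    }
    return m;
  }
};

// ------------------------------------------------------------- bonded ------

static void bonded_forces(const System& S, const Bonded& B, const MinImg& mi,
                          Forces& F) {
  int nb = (int)B.bi.size();
  for (int k = 0; k < nb; ++k) {
    int i = B.bi[k], j = B.bj[k];
    double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j], dz = S.z[i] - S.z[j];
    double dvx = 0.0;
    min_image(mi, dx, dy, dz, dvx);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    double fm = -B.C[k] * (r - B.l0[k]); // restoring toward l0
    double fx = fm * dx / r, fy = fm * dy / r, fz = fm * dz / r;
    F.fx[i] += fx; F.fy[i] += fy; F.fz[i] += fz;
    F.fx[j] -= fx; F.fy[j] -= fy; F.fz[j] -= fz;
    if (F.keep_parts) {
      F.bx[i] += fx; F.by[i] += fy; F.bz[i] += fz;
      F.bx[j] -= fx; F.by[j] -= fy; F.bz[j] -= fz;
    }
  }
  int na = (int)B.ai.size();
  for (int k = 0; k < na; ++k) {
    int i = B.ai[k], j = B.aj[k], l = B.ak[k];
    double ax = S.x[i] - S.x[j], ay = S.y[i] - S.y[j], az = S.z[i] - S.z[j];
    double bx = S.x[l] - S.x[j], by = S.y[l] - S.y[j], bz = S.z[l] - S.z[j];
    double dvx = 0.0;
    min_image(mi, ax, ay, az, dvx);
    dvx = 0.0;
    min_image(mi, bx, by, bz, dvx);
    double la = std::sqrt(ax * ax + ay * ay + az * az);
    double lb = std::sqrt(bx * bx + by * by + bz * bz);
    if (la < 1e-12 || lb < 1e-12) continue;
    double ca = (ax * bx + ay * by + az * bz) / (la * lb);
    ca = std::max(-1.0, std::min(1.0, ca));
    double th = std::acos(ca);
    double s = std::sqrt(std::max(1.0 - ca * ca, 0.0));
    double th0 = B.th0[k] * M_PI / 180.0;
    double dth = th - th0;
    if (std::fabs(dth) < 1e-14) continue;
    double f;
    if (s < 1e-8) {
      // analytic limit near collinearity: (th - pi)/sin(th) -> -1
      f = (th0 > M_PI - 1e-8) ? -B.D[k] : B.D[k] * dth / 1e-8;
    } else {
      f = B.D[k] * dth / s;
    }
    // F_i = f * (b_hat - ca a_hat)/la ; F_l = f * (a_hat - ca b_hat)/lb
    double fix = f * (bx / lb - ca * ax / la) / la;
    double fiy = f * (by / lb - ca * ay / la) / la;
    double fiz = f * (bz / lb - ca * az / la) / la;
    double flx = f * (ax / la - ca * bx / lb) / lb;
    double fly = f * (ay / la - ca * by / lb) / lb;
    double flz = f * (az / la - ca * bz / lb) / lb;
    F.fx[i] += fix; F.fy[i] += fiy; F.fz[i] += fiz;
    F.fx[l] += flx; F.fy[l] += fly; F.fz[l] += flz;
    F.fx[j] -= fix + flx; F.fy[j] -= fiy + fly; F.fz[j] -= fiz + flz;
    if (F.keep_parts) {
      F.ax_[i] += fix; F.ay_[i] += fiy; F.az_[i] += fiz;
      F.ax_[l] += flx; F.ay_[l] += fly; F.az_[l] += flz;
      F.ax_[j] -= fix + flx; F.ay_[j] -= fiy + fly; F.az_[j] -= fiz + flz;
    }
  }
}

// -------------------------------------------------------- electrostatics ---

// real-space part: point-charge Ewald erfc term + short-range Slater
// correction  u_corr = -ke q q (1+br) exp(-2br)/r  (ke = Gamma/4pi)
static void electro_real(const System& S, const ElectroParams& E,
                         const MinImg& mi, bool use_cells, Forces& F) {
  double ke = E.coupling / (4.0 * M_PI);
  double a = E.alpha, b = E.beta;
  const double twosq = 2.0 / std::sqrt(M_PI);
  for_pairs(S, E.rcut, use_cells, mi.shear_offset != 0.0, [&](int i, int j) {
    double qq = S.q[i] * S.q[j];
    if (qq == 0.0) return;
    double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j], dz = S.z[i] - S.z[j];
    double dvx = 0.0;
    min_image(mi, dx, dy, dz, dvx);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= E.rcut * E.rcut || r2 < 1e-20) return;
    double r = std::sqrt(r2);
    double er = std::erfc(a * r);
    double e_point = ke * qq * er / r;
    double f_point = ke * qq * (er / r2 + twosq * a * std::exp(-a * a * r2) / r);
    double ebr = std::exp(-2.0 * b * r);
    double g = (1.0 + b * r) * ebr / r;
    double gp = ebr * (-(b + 2.0 * b * b * r) / r - (1.0 + b * r) / r2);
    double e_corr = -ke * qq * g;
    double f_corr = ke * qq * gp; // F = -dU/dr with U = -ke qq g
    F.e_elec += e_point + e_corr;
    double fm = f_point + f_corr;
    double fx = fm * dx / r, fy = fm * dy / r, fz = fm * dz / r;
    F.fx[i] += fx; F.fy[i] += fy; F.fz[i] += fz;
    F.fx[j] -= fx; F.fy[j] -= fy; F.fz[j] -= fz;
    if (F.keep_parts) {
      F.ex[i] += fx; F.ey[i] += fy; F.ez[i] += fz;
      F.ex[j] -= fx; F.ey[j] -= fy; F.ez[j] -= fz;
    }
  });
}

static void electro_recip(const System& S, const ElectroParams& E, Forces& F) {
  double ke = E.coupling / (4.0 * M_PI);
  double V = S.L * S.L * S.L;
  double pre = ke * 2.0 * M_PI / V;
  double a2 = E.alpha * E.alpha;
  int km = E.kmax;
  double twoPiL = 2.0 * M_PI / S.L;
  std::vector<int> cidx;
  for (int i = 0; i < S.N; ++i)
    if (S.q[i] != 0.0) cidx.push_back(i);
  int M = (int)cidx.size();
  if (M == 0) return;
  std::vector<double> cr(M), ci(M);
  for (int kx = -km; kx <= km; ++kx)
    for (int ky = -km; ky <= km; ++ky)
      for (int kz = -km; kz <= km; ++kz) {
        int k2i = kx * kx + ky * ky + kz * kz;
        if (k2i == 0 || k2i > km * km) continue;
        double gx = twoPiL * kx, gy = twoPiL * ky, gz = twoPiL * kz;
        double k2 = gx * gx + gy * gy + gz * gz;
        double Ak = std::exp(-k2 / (4.0 * a2)) / k2;
        double sr = 0.0, si = 0.0;
        for (int m = 0; m < M; ++m) {
          int i = cidx[m];
          double ph = gx * S.x[i] + gy * S.y[i] + gz * S.z[i];
          cr[m] = std::cos(ph); ci[m] = std::sin(ph);
          sr += S.q[i] * cr[m];
          si += S.q[i] * ci[m];
        }
        F.e_elec += pre * Ak * (sr * sr + si * si);
        for (int m = 0; m < M; ++m) {
          int i = cidx[m];
          double fm = 2.0 * pre * Ak * S.q[i] * (ci[m] * sr - cr[m] * si);
          F.fx[i] += fm * gx; F.fy[i] += fm * gy; F.fz[i] += fm * gz;
          if (F.keep_parts) {
            F.ex[i] += fm * gx; F.ey[i] += fm * gy; F.ez[i] += fm * gz;
          }
        }
      }
  // self energy
  double sq2 = 0.0;
  for (int m = 0; m < M; ++m) sq2 += S.q[cidx[m]] * S.q[cidx[m]];
  F.e_elec -= ke * E.alpha / std::sqrt(M_PI) * sq2;
}

// --------------------------------------------------------- full forces -----

static void compute_forces(const System& S, const FFParams& ff,
                           const Bonded& B, const ElectroParams& E,
                           uint64_t seed, uint64_t step, bool use_cells,
                           Forces& F, bool parts,
                           const NeighList* nl = nullptr) {
  F.init(S.N, parts);
  MinImg mi{S.L, S.shear_offset, S.shear_rate * S.L};
  if (nl) {
    size_t np = nl->pi.size();
    for (size_t k = 0; k < np; ++k) {
      pair_dpd(S, ff, mi, F, seed, step, nl->pi[k], nl->pj[k]);
    }
  } else {
    for_pairs(S, ff.max_cut, use_cells, S.shear_offset != 0.0,
              [&](int i, int j) { pair_dpd(S, ff, mi, F, seed, step, i, j); });
  }
  bonded_forces(S, B, mi, F);
  if (E.enabled) {
    electro_real(S, E, mi, use_cells, F);
    electro_recip(S, E, F);
  }
}

// ------------------------------------------------------------ conversion ---

static System sys_from_r(NumericMatrix x, NumericMatrix v, IntegerVector spec,
                         NumericVector q, double L, double shear_offset,
                         double shear_rate) {
  System S;
  S.N = x.nrow();
  S.x.resize(S.N); S.y.resize(S.N); S.z.resize(S.N);
  S.vx.resize(S.N); S.vy.resize(S.N); S.vz.resize(S.N);
  S.spec.resize(S.N); S.q.resize(S.N);
  for (int i = 0; i < S.N; ++i) {
    S.x[i] = x(i, 0); S.y[i] = x(i, 1); S.z[i] = x(i, 2);
    S.vx[i] = v(i, 0); S.vy[i] = v(i, 1); S.vz[i] = v(i, 2);
    S.spec[i] = spec[i] - 1;
    S.q[i] = q[i];
  }
  S.L = L;
  S.shear_offset = shear_offset;
  S.shear_rate = shear_rate;
  return S;
}

static FFParams ff_from_r(NumericMatrix aij, NumericMatrix Rij, double sigma,
                          double gamma, double dt) {
  FFParams ff;
  ff.nspec = aij.nrow();
  ff.aij.resize(ff.nspec * ff.nspec);
  ff.Rij.resize(ff.nspec * ff.nspec);
  ff.Rij2.resize(ff.nspec * ff.nspec);
  ff.invRij.resize(ff.nspec * ff.nspec);
  ff.max_cut = 0.0;
  for (int a = 0; a < ff.nspec; ++a)
    for (int b = 0; b < ff.nspec; ++b) {
      int ab = a * ff.nspec + b;
      ff.aij[ab] = aij(a, b);
      ff.Rij[ab] = Rij(a, b);
      ff.Rij2[ab] = Rij(a, b) * Rij(a, b);
      ff.invRij[ab] = 1.0 / Rij(a, b);
      ff.max_cut = std::max(ff.max_cut, Rij(a, b));
    }
  ff.sigma = sigma; ff.gamma = gamma; ff.dt = dt;
  ff.inv_sqrt_dt = 1.0 / std::sqrt(dt);
  return ff;
}

static Bonded bonded_from_r(IntegerMatrix bonds, NumericVector l0,
                            NumericVector C, IntegerMatrix angles,
                            NumericVector th0, NumericVector D) {
  Bonded B;
  for (int k = 0; k < bonds.nrow(); ++k) {
    B.bi.push_back(bonds(k, 0) - 1);
    B.bj.push_back(bonds(k, 1) - 1);
    B.l0.push_back(l0[k]);
    B.C.push_back(C[k]);
  }
  for (int k = 0; k < angles.nrow(); ++k) {
    B.ai.push_back(angles(k, 0) - 1);
    B.aj.push_back(angles(k, 1) - 1);
    B.ak.push_back(angles(k, 2) - 1);
    B.th0.push_back(th0[k]);
    B.D.push_back(D[k]);
  }
  return B;
}

static ElectroParams electro_from_r(List e) {
  ElectroParams E;
  if (e.size() == 0) return E;
  E.enabled = as<bool>(e["enabled"]);
  if (!E.enabled) return E;
  E.coupling = as<double>(e["coupling"]);
  E.beta = as<double>(e["beta"]);
  E.alpha = as<double>(e["alpha"]);
  E.rcut = as<double>(e["rcut"]);
  E.kmax = as<int>(e["kmax"]);
  return E;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix x, NumericMatrix v, IntegerVector spec,
                NumericVector q, double L, double shear_offset,
                double shear_rate, NumericMatrix aij, NumericMatrix Rij,
                double sigma, double gamma, double dt, IntegerMatrix bonds,
                NumericVector bond_l0, NumericVector bond_C,
                IntegerMatrix angles, NumericVector angle_th0,
                NumericVector angle_D, List electro, double seed, double step,
                bool use_cells, bool breakdown) {
  System S = sys_from_r(x, v, spec, q, L, shear_offset, shear_rate);
  FFParams ff = ff_from_r(aij, Rij, sigma, gamma, dt);
  Bonded B = bonded_from_r(bonds, bond_l0, bond_C, angles, angle_th0, angle_D);
  ElectroParams E = electro_from_r(electro);
  Forces F;
  compute_forces(S, ff, B, E, (uint64_t)seed, (uint64_t)step, use_cells, F,
                 breakdown);
  int N = S.N;
  NumericMatrix out(N, 3);
  for (int i = 0; i < N; ++i) {
    out(i, 0) = F.fx[i]; out(i, 1) = F.fy[i]; out(i, 2) = F.fz[i];
  }
  List res = List::create(_["force"] = out, _["energy_elec"] = F.e_elec);
  if (breakdown) {
    auto mk = [&](std::vector<double>& a, std::vector<double>& b,
                  std::vector<double>& c) {
      NumericMatrix m(N, 3);
      for (int i = 0; i < N; ++i) { m(i,0)=a[i]; m(i,1)=b[i]; m(i,2)=c[i]; }
      return m;
    };
    res["conservative"] = mk(F.cx, F.cy, F.cz);
    res["dissipative"] = mk(F.dx_, F.dy_, F.dz_);
    res["random"] = mk(F.rx, F.ry, F.rz);
    res["bond"] = mk(F.bx, F.by, F.bz);
    res["angle"] = mk(F.ax_, F.ay_, F.az_);
    res["electrostatic"] = mk(F.ex, F.ey, F.ez);
  }
  return res;
}

// wrap a coordinate into [0, L), Lees-Edwards aware for z crossings
static inline void wrap_particle(System& S, int i) {
  double nz = std::floor(S.z[i] / S.L);
  if (nz != 0.0) {
    S.z[i] -= nz * S.L;
    S.x[i] -= nz * S.shear_offset;
    S.vx[i] -= nz * S.shear_rate * S.L;
  }
  S.x[i] -= S.L * std::floor(S.x[i] / S.L);
  S.y[i] -= S.L * std::floor(S.y[i] / S.L);
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix x, NumericMatrix v, IntegerVector spec,
             NumericVector q, double L, double shear_offset, double shear_rate,
             NumericMatrix aij, NumericMatrix Rij, double sigma, double gamma,
             double dt, IntegerMatrix bonds, NumericVector bond_l0,
             NumericVector bond_C, IntegerMatrix angles,
             NumericVector angle_th0, NumericVector angle_D, List electro,
             double seed, double step0, int nsteps, int stride,
             double lambda, bool use_cells, double time0, int temp_stride,
             NumericMatrix init_force) {
  System S = sys_from_r(x, v, spec, q, L, shear_offset, shear_rate);
  FFParams ff = ff_from_r(aij, Rij, sigma, gamma, dt);
  Bonded B = bonded_from_r(bonds, bond_l0, bond_C, angles, angle_th0, angle_D);
  ElectroParams E = electro_from_r(electro);
  int N = S.N;
  uint64_t sd = (uint64_t)seed;
  Forces F, F2;
  if (init_force.nrow() == N) {
    // restart: resume from the checkpointed force state so the
    // continuation is bitwise identical to an uninterrupted run
    F.init(N, false);
    for (int i = 0; i < N; ++i) {
      F.fx[i] = init_force(i, 0);
      F.fy[i] = init_force(i, 1);
      F.fz[i] = init_force(i, 2);
    }
  }
  const double skin = 0.45;
  NeighList nl;
  nl.build(S, ff.max_cut + skin);
  if (init_force.nrow() != N) {
    compute_forces(S, ff, B, E, sd, (uint64_t)step0, use_cells, F, false,
                   &nl);
  }
  List frames;
  std::vector<double> temps;
  std::vector<double> ttimes;
  auto snapshot = [&](double t) {
    NumericMatrix xs(N, 3), vs(N, 3);
    for (int i = 0; i < N; ++i) {
      xs(i, 0) = S.x[i]; xs(i, 1) = S.y[i]; xs(i, 2) = S.z[i];
      vs(i, 0) = S.vx[i]; vs(i, 1) = S.vy[i]; vs(i, 2) = S.vz[i];
    }
    frames.push_back(List::create(_["positions"] = xs, _["velocities"] = vs,
                                  _["time"] = t,
                                  _["shear_offset"] = S.shear_offset));
  };
  if (stride > 0) snapshot(time0);
  std::vector<double> vx0(N), vy0(N), vz0(N);
  for (int s = 1; s <= nsteps; ++s) {
    uint64_t step = (uint64_t)step0 + (uint64_t)s;
    // Groot-Warren modified velocity-Verlet (unit mass)
    for (int i = 0; i < N; ++i) {
      S.x[i] += dt * S.vx[i] + 0.5 * dt * dt * F.fx[i];
      S.y[i] += dt * S.vy[i] + 0.5 * dt * dt * F.fy[i];
      S.z[i] += dt * S.vz[i] + 0.5 * dt * dt * F.fz[i];
    }
    if (shear_rate != 0.0) {
      double so = S.shear_offset + shear_rate * L * dt;
      S.shear_offset = so - L * std::floor(so / L);
    }
    for (int i = 0; i < N; ++i) wrap_particle(S, i);
    if (nl.max_disp2(S) > 0.25 * skin * skin ||
        std::fabs(S.shear_offset - nl.so0) > 0.25 * skin) {
      nl.build(S, ff.max_cut + skin);
    }
    // predicted velocities for the dissipative force
    std::copy(S.vx.begin(), S.vx.end(), vx0.begin());
    std::copy(S.vy.begin(), S.vy.end(), vy0.begin());
    std::copy(S.vz.begin(), S.vz.end(), vz0.begin());
    for (int i = 0; i < N; ++i) {
      S.vx[i] += lambda * dt * F.fx[i];
      S.vy[i] += lambda * dt * F.fy[i];
      S.vz[i] += lambda * dt * F.fz[i];
    }
    compute_forces(S, ff, B, E, sd, step, use_cells, F2, false, &nl);
    for (int i = 0; i < N; ++i) {
      S.vx[i] = vx0[i] + 0.5 * dt * (F.fx[i] + F2.fx[i]);
      S.vy[i] = vy0[i] + 0.5 * dt * (F.fy[i] + F2.fy[i]);
      S.vz[i] = vz0[i] + 0.5 * dt * (F.fz[i] + F2.fz[i]);
    }
    std::swap(F.fx, F2.fx); std::swap(F.fy, F2.fy); std::swap(F.fz, F2.fz);
    for (int i = 0; i < N; ++i) {
      if (!std::isfinite(F.fx[i]) || !std::isfinite(F.fy[i]) ||
          !std::isfinite(F.fz[i]))
        stop("non-finite force at step %d, bead %d", s, i + 1);
    }
    if (temp_stride > 0 && s % temp_stride == 0) {
      double ke = 0.0;
      for (int i = 0; i < N; ++i)
        ke += S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] + S.vz[i] * S.vz[i];
      temps.push_back(ke / (3.0 * N - 3.0));
      ttimes.push_back(time0 + s * dt);
    }
    if (stride > 0 && s % stride == 0) snapshot(time0 + s * dt);
  }
  NumericMatrix xs(N, 3), vs(N, 3);
  for (int i = 0; i < N; ++i) {
    xs(i, 0) = S.x[i]; xs(i, 1) = S.y[i]; xs(i, 2) = S.z[i];
    vs(i, 0) = S.vx[i]; vs(i, 1) = S.vy[i]; vs(i, 2) = S.vz[i];
  }
  NumericMatrix fs(N, 3);
  for (int i = 0; i < N; ++i) {
    fs(i, 0) = F.fx[i]; fs(i, 1) = F.fy[i]; fs(i, 2) = F.fz[i];
  }
  return List::create(
      _["positions"] = xs, _["velocities"] = vs, _["force"] = fs,
      _["time"] = time0 + nsteps * dt, _["shear_offset"] = S.shear_offset,
      _["step"] = step0 + nsteps, _["frames"] = frames,
      _["temperature"] = NumericVector(temps.begin(), temps.end()),
      _["temperature_time"] = NumericVector(ttimes.begin(), ttimes.end()));
}

// all bead pairs within cutoff (minimum image, optional subset), 1-based ids
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(NumericMatrix x, double L, double cutoff,
                                IntegerVector subset) {
  int M = subset.size();
  System S;
  S.N = M;
  S.x.resize(M); S.y.resize(M); S.z.resize(M);
  S.vx.assign(M, 0.0); S.vy.assign(M, 0.0); S.vz.assign(M, 0.0);
  S.spec.assign(M, 0); S.q.assign(M, 0.0);
  for (int m = 0; m < M; ++m) {
    int i = subset[m] - 1;
    double xi = x(i,0), yi = x(i,1), zi = x(i,2);
    xi -= L * std::floor(xi / L); yi -= L * std::floor(yi / L);
    zi -= L * std::floor(zi / L);
    S.x[m] = xi; S.y[m] = yi; S.z[m] = zi;
  }
  S.L = L; S.shear_offset = 0.0; S.shear_rate = 0.0;
  MinImg mi{L, 0.0, 0.0};
  std::vector<int> pi, pj;
  double c2 = cutoff * cutoff;
  for_pairs(S, cutoff, true, false, [&](int i, int j) {
    double dx = S.x[i]-S.x[j], dy = S.y[i]-S.y[j], dz = S.z[i]-S.z[j], dvx=0.0;
    min_image(mi, dx, dy, dz, dvx);
    if (dx*dx + dy*dy + dz*dz <= c2) {
      pi.push_back(subset[i]);
      pj.push_back(subset[j]);
    }
  });
  IntegerMatrix out((int)pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    out(k, 0) = pi[k]; out(k, 1) = pj[k];
  }
  return out;
}
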
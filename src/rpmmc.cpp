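// Core numerical kernels for the modified-RPM Monte Carlo engine.
// Units: lengths in Angstrom, energies in k_B T, charges in units of e0.
// model$lB1 is the Bjerrum length at eps_r = 1 for the run temperature, so
// beta*u_coulomb(r) = q_i q_j * (lB1 / eps_r(r)) / r.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <climits>
using namespace Rcpp;

struct Model {
  double d, Delta, eps_c, eps_b, lB1;
};

struct Geom {
  bool slit;
  double L, H, zmax;   // zmax: |z| bound for ion centers in the slit
  double I0;           // patch integral at zero offset (slit only)
  bool has_table;      // precomputed sheet-correction table present
  const double* tab;
  int nxp, nzp;        // nodes per lateral / vertical axis
  double h;            // table spacing
};

static Model as_model(const List& m) {
  Model mm;
  mm.d = as<double>(m["d"]);
  mm.Delta = as<double>(m["delta"]);
  mm.eps_c = as<double>(m["eps_c"]);
  mm.eps_b = as<double>(m["eps_b"]);
  mm.lB1 = as<double>(m["lB1"]);
  return mm;
}

// potential of a uniformly charged square patch (side L, centred at origin,
// unit surface density, Gaussian units without 1/(4 pi eps0)): the double
// integral of 1/|r' - (x,y,z)| over the square. Closed form from the standard
// rectangle antiderivative u*log(v+R) + v*log(u+R) - |z|*atan(uv/(|z|R)).
// [[Rcpp::export]]
double cpp_patch_integral(double x, double y, double z, double L) {
  const double a = 0.5 * L;
  const double s[2] = { -a - x, a - x };
  const double t[2] = { -a - y, a - y };
  const double az = std::fabs(z);
  double acc = 0.0;
  for (int i = 0; i < 2; ++i) {
    for (int j = 0; j < 2; ++j) {
      const double sg = ((i + j) % 2 == 0) ? 1.0 : -1.0;
      const double u = s[i], v = t[j];
      const double R = std::sqrt(u * u + v * v + z * z);
      double term = 0.0;
      const double eu = v + R, ev = u + R;
      // eu, ev vanish only on the patch boundary with z = 0 (measure zero)
      term += (eu > 0.0) ? u * std::log(eu) : 0.0;
      term += (ev > 0.0) ? v * std::log(ev) : 0.0;
      if (az > 0.0) term -= az * std::atan2(u * v, az * R);
      acc += sg * term;
    }
  }
  return acc;
}

static Geom as_geom(const List& g) {
  Geom gg;
  gg.slit = as<int>(g["slit"]) != 0;
  gg.L = as<double>(g["L"]);
  gg.H = gg.slit ? as<double>(g["H"]) : 0.0;
  gg.zmax = gg.slit ? as<double>(g["zmax"]) : R_PosInf;
  gg.I0 = gg.slit ? cpp_patch_integral(0.0, 0.0, 0.0, gg.L) : 0.0;
  gg.has_table = false;
  gg.tab = nullptr;
  gg.nxp = gg.nzp = 0;
  gg.h = 0.0;
  if (gg.slit && g.containsElementNamed("corr_tab") &&
      !Rf_isNull(g["corr_tab"])) {
    List ct = g["corr_tab"];
    NumericVector tv = ct["table"];
    gg.tab = REAL(tv);
    gg.nxp = as<int>(ct["nxp"]);
    gg.nzp = as<int>(ct["nzp"]);
    gg.h = as<double>(ct["h"]);
    gg.has_table = true;
  }
  return gg;
}

// exp(x^2) * erfc(x), overflow-safe
static inline double erfcx_safe(double x) {
  if (x > 6.0) {
    const double ix2 = 1.0 / (x * x);
    return (1.0 - 0.5 * ix2 * (1.0 - 1.5 * ix2)) / (x * std::sqrt(M_PI));
  }
  return std::exp(x * x) * std::erfc(x);
}

// Interaction of a unit charge with the lateral periodic images (excluding
// the central minimum-image point) of another unit charge, up to an additive
// constant that cancels in electroneutral systems. The dominant term is the
// charged-sheet (laterally smeared) far field; the discreteness of the image
// lattice is restored by the rapidly converging split summation: screened
// real-space image terms plus the Fourier modes of the lattice, so the
// result tracks a brute-force image sum to ~1e-7.
// [[Rcpp::export]]
double cpp_slit_corr(double dx, double dy, double dz, double L) {
  const double alpha = 2.5 / L;
  const double r0 = std::sqrt(dx * dx + dy * dy + dz * dz);
  // subtract the unscreened central point (kept explicitly by the caller)
  double corr = (r0 > 1e-12) ? -std::erf(alpha * r0) / r0
                             : -2.0 * alpha / std::sqrt(M_PI);
  for (int n = -2; n <= 2; ++n)
    for (int m = -2; m <= 2; ++m) {
      if (n == 0 && m == 0) continue;
      const double ux = dx + n * L, uy = dy + m * L;
      const double r = std::sqrt(ux * ux + uy * uy + dz * dz);
      corr += std::erfc(alpha * r) / r;
    }
  const double twopiL = 2.0 * M_PI / L;
  const double az = alpha * dz;
  for (int gn = 0; gn <= 4; ++gn)
    for (int gm = 0; gm <= 4; ++gm) {
      if (gn == 0 && gm == 0) continue;
      if (gn * gn + gm * gm > 16) continue;
      const double G = twopiL * std::sqrt((double)(gn * gn + gm * gm));
      const double expfac = std::exp(-G * G / (4 * alpha * alpha) - az * az);
      const double s = erfcx_safe(az + G / (2 * alpha)) +
                       erfcx_safe(-az + G / (2 * alpha));
      // sum over the four sign combinations of (gn, gm)
      double csum;
      if (gn == 0) csum = 2.0 * std::cos(twopiL * gm * dy);
      else if (gm == 0) csum = 2.0 * std::cos(twopiL * gn * dx);
      else csum = 4.0 * std::cos(twopiL * gn * dx) * std::cos(twopiL * gm * dy);
      corr += (M_PI / (L * L)) * (csum / G) * expfac * s;
    }
  corr -= (2.0 * M_PI / (L * L)) *
          (dz * std::erf(az) + std::exp(-az * az) / (alpha * std::sqrt(M_PI)));
  return corr;
}

// Precompute cpp_slit_corr on a regular grid over |dx|,|dy| <= L/2 and
// |dz| <= zspan (the factor is even in each argument) for trilinear
// interpolation inside the sweep kernels.
// [[Rcpp::export]]
List cpp_slit_corr_table(double L, double zspan, double h) {
  const int nxp = (int)std::ceil((L / 2) / h) + 2;
  const int nzp = (int)std::ceil(zspan / h) + 2;
  NumericVector tab((double)nxp * nxp * nzp);
  for (int iz = 0; iz < nzp; ++iz)
    for (int iy = 0; iy < nxp; ++iy)
      for (int ix = 0; ix < nxp; ++ix)
        tab[((size_t)iz * nxp + iy) * nxp + ix] =
          cpp_slit_corr(ix * h, iy * h, iz * h, L);
  return List::create(_["table"] = tab, _["nxp"] = nxp, _["nzp"] = nzp,
                      _["h"] = h, _["L"] = L, _["zspan"] = zspan);
}

static inline double corr_lookup(const Geom& g, double dx, double dy,
                                 double dz) {
  const double ax = std::fabs(dx) / g.h, ay = std::fabs(dy) / g.h,
               az = std::fabs(dz) / g.h;
  int ix = (int)ax, iy = (int)ay, iz = (int)az;
  if (ix > g.nxp - 2) ix = g.nxp - 2;
  if (iy > g.nxp - 2) iy = g.nxp - 2;
  if (iz > g.nzp - 2) iz = g.nzp - 2;
  const double fx = ax - ix, fy = ay - iy, fz = az - iz;
  const double* t = g.tab;
  const size_t nxp = g.nxp;
  #define TT(a, b, c) t[((size_t)(c) * nxp + (b)) * nxp + (a)]
  const double c00 = TT(ix, iy, iz) * (1 - fx) + TT(ix + 1, iy, iz) * fx;
  const double c10 = TT(ix, iy + 1, iz) * (1 - fx) + TT(ix + 1, iy + 1, iz) * fx;
  const double c01 = TT(ix, iy, iz + 1) * (1 - fx) + TT(ix + 1, iy, iz + 1) * fx;
  const double c11 = TT(ix, iy + 1, iz + 1) * (1 - fx) +
                     TT(ix + 1, iy + 1, iz + 1) * fx;
  #undef TT
  return (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
         (c01 * (1 - fy) + c11 * fy) * fz;
}

static inline double eps_ramp(const Model& m, double r) {
  if (r <= m.d) return m.eps_c;
  if (r >= m.d + m.Delta) return m.eps_b;
  return m.eps_c + (m.eps_b - m.eps_c) * (r - m.d) / m.Delta;
}

// nearest-image component; tie at exactly L/2 resolved to +L/2
static inline double mi1(double dx, double L) {
  double w = dx - L * std::nearbyint(dx / L);
  if (w == -0.5 * L) w = 0.5 * L;
  return w;
}

// beta * u for one pair. For the slit, adds the charged-sheet correction:
// the lateral periodic images beyond minimum image are replaced by an
// infinite uniform sheet minus the central LxL patch, evaluated with eps_b
// and referenced so the correction vanishes as L -> infinity.
static inline double pair_beta_u(const Model& m, const Geom& g,
                                 double xi, double yi, double zi, double qi,
                                 double xj, double yj, double zj, double qj) {
  const double dx = mi1(xi - xj, g.L);
  const double dy = mi1(yi - yj, g.L);
  const double dz = g.slit ? (zi - zj) : mi1(zi - zj, g.L);
  const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (r < m.d) return R_PosInf;
  double u = qi * qj * (m.lB1 / eps_ramp(m, r)) / r;
  if (g.slit) {
    const double cf = g.has_table ? corr_lookup(g, dx, dy, dz)
                                  : cpp_slit_corr(dx, dy, dz, g.L);
    u += qi * qj * (m.lB1 / m.eps_b) * cf;
  }
  return u;
}

// energy of particle i at candidate coordinates (cx,cy,cz)
static double particle_energy_at(const NumericMatrix& pos, const NumericVector& q,
                                 const Model& m, const Geom& g,
                                 int i, double cx, double cy, double cz) {
  const int n = pos.nrow();
  double e = 0.0;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    const double u = pair_beta_u(m, g, cx, cy, cz, q[i],
                                 pos(j, 0), pos(j, 1), pos(j, 2), q[j]);
    if (!R_FINITE(u)) return R_PosInf;
    e += u;
  }
  return e;
}

// interaction of ion i with its own lateral periodic images (slit only);
// position independent, so it never enters move energy differences
static inline double self_image_energy(const Model& m, const Geom& g,
                                       double qi) {
  if (!g.slit) return 0.0;
  return 0.5 * qi * qi * (m.lB1 / m.eps_b) *
         cpp_slit_corr(0.0, 0.0, 0.0, g.L);
}

// [[Rcpp::export]]
double cpp_particle_energy(const NumericMatrix& pos, const NumericVector& q,
                           const List& geom, const List& model, int i0) {
  Model m = as_model(model);
  Geom g = as_geom(geom);
  return particle_energy_at(pos, q, m, g, i0,
                            pos(i0, 0), pos(i0, 1), pos(i0, 2)) +
         2.0 * self_image_energy(m, g, q[i0]);
}

// [[Rcpp::export]]
double cpp_total_energy(const NumericMatrix& pos, const NumericVector& q,
                        const List& geom, const List& model) {
  Model m = as_model(model);
  Geom g = as_geom(geom);
  const int n = pos.nrow();
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    e += self_image_energy(m, g, q[i]);
    for (int j = i + 1; j < n; ++j)
      e += pair_beta_u(m, g, pos(i, 0), pos(i, 1), pos(i, 2), q[i],
                       pos(j, 0), pos(j, 1), pos(j, 2), q[j]);
  }
  return e;
}

// [[Rcpp::export]]
double cpp_min_pair_distance(const NumericMatrix& pos, const List& geom) {
  Geom g = as_geom(geom);
  const int n = pos.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = mi1(pos(i, 0) - pos(j, 0), g.L);
      const double dy = mi1(pos(i, 1) - pos(j, 1), g.L);
      const double dz = g.slit ? (pos(i, 2) - pos(j, 2))
                               : mi1(pos(i, 2) - pos(j, 2), g.L);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < best) best = r;
    }
  return best;
}

static inline double wrap01(double x, double L) {
  return x - L * std::floor(x / L);
}

// connected component containing `seed` under pair distance <= delta;
// aborts (returns false) once the component exceeds `cap` members — used to
// reject oversized cluster moves cheaply (the rejection is symmetric in the
// proposal, so detailed balance is preserved)
static bool build_cluster(const NumericMatrix& pos, const Geom& g,
                          int seed, double delta,
                          std::vector<char>& member, std::vector<int>& out,
                          int cap = INT_MAX) {
  const int n = pos.nrow();
  std::fill(member.begin(), member.end(), 0);
  out.clear();
  std::vector<int> stack;
  stack.push_back(seed);
  member[seed] = 1;
  const double d2 = delta * delta;
  int count = 1;
  while (!stack.empty()) {
    const int i = stack.back();
    stack.pop_back();
    out.push_back(i);
    for (int j = 0; j < n; ++j) {
      if (member[j]) continue;
      const double dx = mi1(pos(i, 0) - pos(j, 0), g.L);
      const double dy = mi1(pos(i, 1) - pos(j, 1), g.L);
      const double dz = g.slit ? (pos(i, 2) - pos(j, 2))
                               : mi1(pos(i, 2) - pos(j, 2), g.L);
      if (dx * dx + dy * dy + dz * dz <= d2) {
        member[j] = 1;
        stack.push_back(j);
        if (++count > cap) return false;
      }
    }
  }
  return true;
}

// cell-list accelerated variant of build_cluster: identical membership,
// neighbor search restricted to the 27 adjacent cells (cell size >= delta)
struct CellGrid {
  int ncx, ncz;          // lateral cells (x and y), vertical cells
  double cx, cz, z0;     // cell sizes; z origin (slit: -zmax)
  bool wrapz;
  std::vector<int> head, nxt;
  void setup(const Geom& g, double delta, int n) {
    ncx = std::max(1, (int)std::floor(g.L / delta));
    cx = g.L / ncx;
    if (g.slit) {
      wrapz = false;
      z0 = -(g.zmax + 1e-9);
      const double span = 2.0 * g.zmax + 2e-9;
      ncz = std::max(1, (int)std::floor(span / delta));
      cz = span / ncz;
    } else {
      wrapz = true;
      z0 = 0.0;
      ncz = ncx;
      cz = cx;
    }
    head.assign((size_t)ncx * ncx * ncz, -1);
    nxt.assign(n, -1);
  }
  inline int clampi(int i, int n) const { return i < 0 ? 0 : (i >= n ? n - 1 : i); }
  inline size_t cell(int ix, int iy, int iz) const {
    return ((size_t)iz * ncx + iy) * ncx + ix;
  }
  void fill(const NumericMatrix& pos) {
    std::fill(head.begin(), head.end(), -1);
    const int n = pos.nrow();
    for (int i = 0; i < n; ++i) {
      const int ix = clampi((int)(pos(i, 0) / cx), ncx);
      const int iy = clampi((int)(pos(i, 1) / cx), ncx);
      const int iz = clampi((int)((pos(i, 2) - z0) / cz), ncz);
      const size_t c = cell(ix, iy, iz);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

static bool build_cluster_cells(const NumericMatrix& pos, const Geom& g,
                                int seed, double delta,
                                std::vector<char>& member,
                                std::vector<int>& out, int cap,
                                CellGrid& grid) {
  grid.fill(pos);
  std::fill(member.begin(), member.end(), 0);
  out.clear();
  std::vector<int> stack;
  stack.push_back(seed);
  member[seed] = 1;
  const double d2 = delta * delta;
  int count = 1;
  while (!stack.empty()) {
    const int i = stack.back();
    stack.pop_back();
    out.push_back(i);
    const int ix = grid.clampi((int)(pos(i, 0) / grid.cx), grid.ncx);
    const int iy = grid.clampi((int)(pos(i, 1) / grid.cx), grid.ncx);
    const int iz = grid.clampi((int)((pos(i, 2) - grid.z0) / grid.cz),
                               grid.ncz);
    for (int dzc = -1; dzc <= 1; ++dzc) {
      int jz = iz + dzc;
      if (grid.wrapz) jz = (jz + grid.ncz) % grid.ncz;
      else if (jz < 0 || jz >= grid.ncz) continue;
      for (int dyc = -1; dyc <= 1; ++dyc) {
        const int jy = (iy + dyc + grid.ncx) % grid.ncx;
        for (int dxc = -1; dxc <= 1; ++dxc) {
          const int jx = (ix + dxc + grid.ncx) % grid.ncx;
          for (int j = grid.head[grid.cell(jx, jy, jz)]; j >= 0;
               j = grid.nxt[j]) {
            if (member[j]) continue;
            const double dx = mi1(pos(i, 0) - pos(j, 0), g.L);
            const double dy = mi1(pos(i, 1) - pos(j, 1), g.L);
            const double dz = g.slit ? (pos(i, 2) - pos(j, 2))
                                     : mi1(pos(i, 2) - pos(j, 2), g.L);
            if (dx * dx + dy * dy + dz * dz <= d2) {
              member[j] = 1;
              stack.push_back(j);
              if (++count > cap) return false;
            }
          }
        }
      }
    }
  }
  return true;
}

// Metropolis sweeps over a mixture of single-particle displacements and rigid
// cluster translations (with the merge-rejection detailed-balance guard).
// All randomness is drawn from R's RNG. Returns the updated configuration,
// the updated running energy, and acceptance counters.
// [[Rcpp::export]]
List cpp_run_sweeps(const NumericMatrix& pos_in, const NumericVector& q,
                    const List& geom, const List& model,
                    int nsweeps, double step, double p_cluster,
                    double cluster_step, double delta_mv, double U0,
                    int cluster_max) {
  Model m = as_model(model);
  Geom g = as_geom(geom);
  NumericMatrix pos = clone(pos_in);
  const int n = pos.nrow();
  double U = U0;
  long att_d = 0, acc_d = 0, att_c = 0, acc_c = 0;
  std::vector<char> member(n);
  std::vector<int> cl;
  std::vector<double> nx(n), ny(n), nz(n);
  CellGrid grid;
  if (p_cluster > 0.0 && n > 0) grid.setup(g, delta_mv, n);
  RNGScope scope;

  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    for (int k = 0; k < n; ++k) {
      const bool do_cluster = (p_cluster > 0.0) && (unif_rand() < p_cluster);
      int i = (int)(unif_rand() * n);
      if (i >= n) i = n - 1;

      if (!do_cluster) {
        ++att_d;
        double cx = pos(i, 0) + step * (2.0 * unif_rand() - 1.0);
        double cy = pos(i, 1) + step * (2.0 * unif_rand() - 1.0);
        double cz = pos(i, 2) + step * (2.0 * unif_rand() - 1.0);
        cx = wrap01(cx, g.L);
        cy = wrap01(cy, g.L);
        if (g.slit) {
          if (std::fabs(cz) > g.zmax) continue;  // hard wall
        } else {
          cz = wrap01(cz, g.L);
        }
        const double un = particle_energy_at(pos, q, m, g, i, cx, cy, cz);
        if (!R_FINITE(un)) continue;  // hard-core overlap
        const double uo = particle_energy_at(pos, q, m, g, i,
                                             pos(i, 0), pos(i, 1), pos(i, 2));
        const double dU = un - uo;
        if (dU <= 0.0 || unif_rand() < std::exp(-dU)) {
          pos(i, 0) = cx; pos(i, 1) = cy; pos(i, 2) = cz;
          U += dU;
          ++acc_d;
        }
      } else {
        ++att_c;
        if (!build_cluster_cells(pos, g, i, delta_mv, member, cl, cluster_max,
                                 grid))
          continue;  // oversized cluster: symmetric rejection
        const double tx = cluster_step * (2.0 * unif_rand() - 1.0);
        const double ty = cluster_step * (2.0 * unif_rand() - 1.0);
        const double tz = cluster_step * (2.0 * unif_rand() - 1.0);
        bool reject = false;
        for (size_t a = 0; a < cl.size(); ++a) {
          const int mi = cl[a];
          nx[mi] = wrap01(pos(mi, 0) + tx, g.L);
          ny[mi] = wrap01(pos(mi, 1) + ty, g.L);
          nz[mi] = pos(mi, 2) + tz;
          if (g.slit) {
            if (std::fabs(nz[mi]) > g.zmax) { reject = true; break; }
          } else {
            nz[mi] = wrap01(nz[mi], g.L);
          }
        }
        // merge guard: the translated cluster must not acquire new members
        // (delta_mv >= d, so this also covers hard-core overlaps)
        const double dm2 = delta_mv * delta_mv;
        double dU = 0.0;
        if (!reject) {
          for (size_t a = 0; a < cl.size() && !reject; ++a) {
            const int mi = cl[a];
            for (int j = 0; j < n; ++j) {
              if (member[j]) continue;
              const double dx = mi1(nx[mi] - pos(j, 0), g.L);
              const double dy = mi1(ny[mi] - pos(j, 1), g.L);
              const double dz = g.slit ? (nz[mi] - pos(j, 2))
                                       : mi1(nz[mi] - pos(j, 2), g.L);
              if (dx * dx + dy * dy + dz * dz <= dm2) { reject = true; break; }
              dU += pair_beta_u(m, g, nx[mi], ny[mi], nz[mi], q[mi],
                                pos(j, 0), pos(j, 1), pos(j, 2), q[j]) -
                    pair_beta_u(m, g, pos(mi, 0), pos(mi, 1), pos(mi, 2), q[mi],
                                pos(j, 0), pos(j, 1), pos(j, 2), q[j]);
            }
          }
        }
        if (!reject && (dU <= 0.0 || unif_rand() < std::exp(-dU))) {
          for (size_t a = 0; a < cl.size(); ++a) {
            const int mi = cl[a];
            pos(mi, 0) = nx[mi]; pos(mi, 1) = ny[mi]; pos(mi, 2) = nz[mi];
          }
          U += dU;
          ++acc_c;
        }
      }
    }
  }
  return List::create(_["pos"] = pos, _["energy"] = U,
                      _["att_disp"] = (double)att_d, _["acc_disp"] = (double)acc_d,
                      _["att_cluster"] = (double)att_c, _["acc_cluster"] = (double)acc_c);
}

// raw pair counts for species-resolved RDFs (bulk, full minimum image);
// column 1: like pairs (++ pooled with --), column 2: unlike pairs
// [[Rcpp::export]]
NumericMatrix cpp_pair_counts(const NumericMatrix& pos, const NumericVector& q,
                              double L, int nbins, double dr) {
  const int n = pos.nrow();
  NumericMatrix counts(nbins, 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = mi1(pos(i, 0) - pos(j, 0), L);
      const double dy = mi1(pos(i, 1) - pos(j, 1), L);
      const double dz = mi1(pos(i, 2) - pos(j, 2), L);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const int b = (int)(r / dr);
      if (b >= 0 && b < nbins) {
        if (q[i] * q[j] > 0) counts(b, 0) += 1.0; else counts(b, 1) += 1.0;
      }
    }
  return counts;
}

// cluster labels (1-based, in order of first discovery) under distance <= delta
// [[Rcpp::export]]
IntegerVector cpp_cluster_labels(const NumericMatrix& pos, const List& geom,
                                 double delta) {
  Geom g = as_geom(geom);
  const int n = pos.nrow();
  IntegerVector lab(n, 0);
  std::vector<char> member(n);
  std::vector<int> comp;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (lab[i] != 0) continue;
    ++next;
    build_cluster(pos, g, i, delta, member, comp);
    for (size_t a = 0; a < comp.size(); ++a) lab[comp[a]] = next;
  }
  return lab;
}

// ghost +q/-q pair insertions at separations rks into a bulk frame;
// returns the sum over insertions of exp(-beta dU) for each separation
// (hard-core-overlapping insertions contribute zero)
// [[Rcpp::export]]
NumericVector cpp_widom_pair(const NumericMatrix& pos, const NumericVector& q,
                             const List& geom, const List& model,
                             const NumericVector& rks, int ninsert,
                             double qtest) {
  Model m = as_model(model);
  Geom g = as_geom(geom);
  const int n = pos.nrow();
  const int nk = rks.size();
  NumericVector s(nk);
  RNGScope scope;
  if (qtest == 0.0) {  // null perturbation: w is identically zero
    for (int k = 0; k < nk; ++k) s[k] = ninsert;
    return s;
  }
  for (int k = 0; k < nk; ++k) {
    const double rk = rks[k];  // caller enforces d < rk < L/2
    const double ugg = -qtest * qtest * (m.lB1 / eps_ramp(m, rk)) / rk;
    double acc = 0.0;
    for (int t = 0; t < ninsert; ++t) {
      const double x1 = g.L * unif_rand();
      const double y1 = g.L * unif_rand();
      const double z1 = g.L * unif_rand();
      const double ct = 2.0 * unif_rand() - 1.0;
      const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      const double ph = 2.0 * M_PI * unif_rand();
      const double x2 = wrap01(x1 + rk * st * std::cos(ph), g.L);
      const double y2 = wrap01(y1 + rk * st * std::sin(ph), g.L);
      const double z2 = wrap01(z1 + rk * ct, g.L);
      double du = ugg;
      bool ok = true;
      for (int j = 0; j < n && ok; ++j) {
        const double u1 = pair_beta_u(m, g, x1, y1, z1, qtest,
                                      pos(j, 0), pos(j, 1), pos(j, 2), q[j]);
        if (!R_FINITE(u1)) { ok = false; break; }
        const double u2 = pair_beta_u(m, g, x2, y2, z2, -qtest,
                                      pos(j, 0), pos(j, 1), pos(j, 2), q[j]);
        if (!R_FINITE(u2)) { ok = false; break; }
        du += u1 + u2;
      }
      if (ok) acc += std::exp(-du);
    }
    s[k] = acc;
  }
  return s;
}
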
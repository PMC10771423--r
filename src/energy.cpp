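#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Simplified nonbonded protein-ligand model:
//   LJ 12-6 with Lorentz-Berthelot combining (eps_ij = sqrt(eps_i*eps_j),
//   rmin_ij = (rmin_i + rmin_j)/2) plus Coulomb with distance-dependent
//   dielectric eps(r) = 4r, i.e. E_c = KELEC*q_i*q_j/(4*r^2).
//   Every pair term is shifted so it vanishes exactly at the cutoff.
// All distances in Angstrom, energies in kcal/mol, charges in elementary units.

static const double KELEC = 332.0636; // kcal*A/(mol*e^2)

// per protein-ligand pair constants, flattened as [i*nl + j]
struct PairTable {
  int np, nl;
  double rc2;
  std::vector<double> eps;    // eps_ij
  std::vector<double> rmin2;  // rmin_ij^2
  std::vector<double> kqq;    // KELEC/4 * q_i * q_j
  std::vector<double> shift;  // unshifted pair energy at the cutoff
  std::vector<double> px;     // protein coords, [3*i]
};

static PairTable build_table(const NumericMatrix &px, const NumericVector &pq,
                             const NumericVector &peps, const NumericVector &prmin,
                             const NumericVector &lq, const NumericVector &leps,
                             const NumericVector &lrmin, double cutoff) {
  PairTable t;
  t.np = px.nrow();
  t.nl = lq.size();
  t.rc2 = cutoff * cutoff;
  size_t n = (size_t)t.np * t.nl;
  t.eps.resize(n);
  t.rmin2.resize(n);
  t.kqq.resize(n);
  t.shift.resize(n);
  t.px.resize(3 * t.np);
  for (int i = 0; i < t.np; ++i) {
    t.px[3 * i] = px(i, 0);
    t.px[3 * i + 1] = px(i, 1);
    t.px[3 * i + 2] = px(i, 2);
    for (int j = 0; j < t.nl; ++j) {
      size_t k = (size_t)i * t.nl + j;
      double e = std::sqrt(peps[i] * leps[j]);
      double rm = 0.5 * (prmin[i] + lrmin[j]);
      t.eps[k] = e;
      t.rmin2[k] = rm * rm;
      t.kqq[k] = (KELEC / 4.0) * pq[i] * lq[j];
      double a = t.rmin2[k] / t.rc2;
      double a3 = a * a * a;
      t.shift[k] = e * (a3 * a3 - 2.0 * a3) + t.kqq[k] / t.rc2;
    }
  }
  return t;
}

static inline double pair_e(const PairTable &t, size_t k, double r2) {
  double a = t.rmin2[k] / r2;
  double a3 = a * a * a;
  return t.eps[k] * (a3 * a3 - 2.0 * a3) + t.kqq[k] / r2 - t.shift[k];
}

static double table_energy(const PairTable &t, const double *lx) {
  double tot = 0.0;
  for (int i = 0; i < t.np; ++i) {
    double xi = t.px[3 * i], yi = t.px[3 * i + 1], zi = t.px[3 * i + 2];
    size_t base = (size_t)i * t.nl;
    for (int j = 0; j < t.nl; ++j) {
      double dx = xi - lx[3 * j], dy = yi - lx[3 * j + 1], dz = zi - lx[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < t.rc2) tot += pair_e(t, base + j, r2);
    }
  }
  return tot;
}

// [[Rcpp::export]]
NumericVector cpp_interaction_energy(NumericMatrix px, NumericVector pq,
                                     NumericVector peps, NumericVector prmin,
                                     NumericMatrix lx, NumericVector lq,
                                     NumericVector leps, NumericVector lrmin,
                                     double cutoff) {
  int np = px.nrow(), nl = lx.nrow();
  double rc2 = cutoff * cutoff;
  double lj = 0.0, coul = 0.0;
  for (int i = 0; i < np; ++i) {
    double xi = px(i, 0), yi = px(i, 1), zi = px(i, 2);
    for (int j = 0; j < nl; ++j) {
      double dx = xi - lx(j, 0), dy = yi - lx(j, 1), dz = zi - lx(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      double epsij = std::sqrt(peps[i] * leps[j]);
      double rminij = 0.5 * (prmin[i] + lrmin[j]);
      double rmin2 = rminij * rminij;
      double qq = (KELEC / 4.0) * pq[i] * lq[j];
      double a = rmin2 / r2, ac = rmin2 / rc2;
      double a3 = a * a * a, ac3 = ac * ac * ac;
      lj += epsij * ((a3 * a3 - 2.0 * a3) - (ac3 * ac3 - 2.0 * ac3));
      coul += qq / r2 - qq / rc2;
    }
  }
  return NumericVector::create(_["lj"] = lj, _["coulomb"] = coul,
                               _["total"] = lj + coul);
}

static void table_gradient(const PairTable &t, const double *lx,
                           const double *center, double *g) {
  for (int k = 0; k < 6; ++k) g[k] = 0.0;
  for (int j = 0; j < t.nl; ++j) {
    double gx = 0.0, gy = 0.0, gz = 0.0;
    double xj = lx[3 * j], yj = lx[3 * j + 1], zj = lx[3 * j + 2];
    for (int i = 0; i < t.np; ++i) {
      double dx = xj - t.px[3 * i], dy = yj - t.px[3 * i + 1],
             dz = zj - t.px[3 * i + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= t.rc2) continue;
      size_t k = (size_t)i * t.nl + j;
      double a = t.rmin2[k] / r2;
      double a2 = a * a;
      double a5 = a2 * a2 * a;
      double dudr2 = -6.0 * t.eps[k] * t.rmin2[k] / (r2 * r2) * (a5 - a2)
                     - t.kqq[k] / (r2 * r2);
      double f = 2.0 * dudr2;
      gx += f * dx;
      gy += f * dy;
      gz += f * dz;
    }
    g[0] += gx;
    g[1] += gy;
    g[2] += gz;
    double ox = xj - center[0], oy = yj - center[1], oz = zj - center[2];
    g[3] += oy * gz - oz * gy;
    g[4] += oz * gx - ox * gz;
    g[5] += ox * gy - oy * gx;
  }
}

// gradient of the total energy w.r.t. rigid-body dof of the ligand:
// first 3 components d E/d t (translation), last 3 d E/d omega for an
// infinitesimal rotation about `center`.
// [[Rcpp::export]]
NumericVector cpp_rigid_gradient(NumericMatrix px, NumericVector pq,
                                 NumericVector peps, NumericVector prmin,
                                 NumericMatrix lx, NumericVector lq,
                                 NumericVector leps, NumericVector lrmin,
                                 double cutoff, NumericVector center) {
  PairTable t = build_table(px, pq, peps, prmin, lq, leps, lrmin, cutoff);
  int nl = lx.nrow();
  std::vector<double> X(3 * nl);
  for (int j = 0; j < nl; ++j)
    for (int k = 0; k < 3; ++k) X[3 * j + k] = lx(j, k);
  double c[3] = {center[0], center[1], center[2]};
  NumericVector g(6);
  double gg[6];
  table_gradient(t, X.data(), c, gg);
  for (int k = 0; k < 6; ++k) g[k] = gg[k];
  return g;
}

static inline void rodrigues(const double *w, double R[3][3]) {
  double th = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (th < 1e-14) {
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) R[i][j] = (i == j) ? 1.0 : 0.0;
    return;
  }
  double kx = w[0] / th, ky = w[1] / th, kz = w[2] / th;
  double c = std::cos(th), s = std::sin(th), v = 1.0 - c;
  R[0][0] = c + kx * kx * v;      R[0][1] = kx * ky * v - kz * s; R[0][2] = kx * kz * v + ky * s;
  R[1][0] = ky * kx * v + kz * s; R[1][1] = c + ky * ky * v;      R[1][2] = ky * kz * v - kx * s;
  R[2][0] = kz * kx * v - ky * s; R[2][1] = kz * ky * v + kx * s; R[2][2] = c + kz * kz * v;
}

// rigid-body gradient descent with backtracking (Armijo) line search.
// Returns final ligand coords, the accumulated rotation applied about the
// (moving) ligand centroid, the final energy and convergence diagnostics.
// The energy trace is monotone non-increasing by construction.
// [[Rcpp::export]]
List cpp_minimize(NumericMatrix px, NumericVector pq, NumericVector peps,
                  NumericVector prmin, NumericMatrix lx0, NumericVector lq,
                  NumericVector leps, NumericVector lrmin, double cutoff,
                  int max_iter = 200, double gtol = 1e-3) {
  PairTable t = build_table(px, pq, peps, prmin, lq, leps, lrmin, cutoff);
  int nl = lx0.nrow();
  std::vector<double> X(3 * nl), Xn(3 * nl);
  for (int j = 0; j < nl; ++j)
    for (int k = 0; k < 3; ++k) X[3 * j + k] = lx0(j, k);
  double Rtot[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  double E = table_energy(t, X.data());
  double gnorm = NA_REAL;
  int it = 0;
  bool converged = false;
  int stall = 0; // consecutive iterations with negligible energy progress
  double g[6];
  for (it = 0; it < max_iter; ++it) {
    double c[3] = {0, 0, 0};
    for (int j = 0; j < nl; ++j) {
      c[0] += X[3 * j]; c[1] += X[3 * j + 1]; c[2] += X[3 * j + 2];
    }
    c[0] /= nl; c[1] /= nl; c[2] /= nl;
    table_gradient(t, X.data(), c, g);
    double g2 = 0;
    for (int k = 0; k < 6; ++k) g2 += g[k] * g[k];
    gnorm = std::sqrt(g2);
    if (gnorm < gtol) { converged = true; break; }
    // initial step: cap the typical displacement near 0.5 A
    double alpha = 0.5 / (gnorm + 1e-12);
    if (alpha > 0.25) alpha = 0.25;
    bool moved = false;
    for (int bt = 0; bt < 40; ++bt) {
      double w[3] = {-alpha * g[3], -alpha * g[4], -alpha * g[5]};
      double Rs[3][3];
      rodrigues(w, Rs);
      for (int j = 0; j < nl; ++j) {
        double ox = X[3 * j] - c[0], oy = X[3 * j + 1] - c[1], oz = X[3 * j + 2] - c[2];
        Xn[3 * j]     = Rs[0][0] * ox + Rs[0][1] * oy + Rs[0][2] * oz + c[0] - alpha * g[0];
        Xn[3 * j + 1] = Rs[1][0] * ox + Rs[1][1] * oy + Rs[1][2] * oz + c[1] - alpha * g[1];
        Xn[3 * j + 2] = Rs[2][0] * ox + Rs[2][1] * oy + Rs[2][2] * oz + c[2] - alpha * g[2];
      }
      double En = table_energy(t, Xn.data());
      if (En <= E - 1e-4 * alpha * g2) {
        // energy-progress stop: the gradient norm can stay large while the
        // line search zig-zags in the stiff core region; once the energy is
        // no longer improving meaningfully the pose is effectively minimized
        if (E - En < 1e-5 * (1.0 + std::fabs(E))) {
          ++stall;
        } else {
          stall = 0;
        }
        X.swap(Xn);
        E = En;
        double Rn[3][3];
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b)
            Rn[a][b] = Rs[a][0] * Rtot[0][b] + Rs[a][1] * Rtot[1][b] + Rs[a][2] * Rtot[2][b];
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b) Rtot[a][b] = Rn[a][b];
        moved = true;
        break;
      }
      alpha *= 0.5;
    }
    if (!moved) break; // line search exhausted: local stationarity
    if (stall >= 2) { converged = true; break; }
  }
  NumericMatrix xout(nl, 3), rot(3, 3);
  for (int j = 0; j < nl; ++j)
    for (int k = 0; k < 3; ++k) xout(j, k) = X[3 * j + k];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) rot(a, b) = Rtot[a][b];
  return List::create(_["coords"] = xout, _["rotation"] = rot, _["energy"] = E,
                      _["grad_norm"] = gnorm, _["iterations"] = it,
                      _["converged"] = converged);
}

static inline void mat_to_quat(const double R[3][3], double q[4]) {
  double tr = R[0][0] + R[1][1] + R[2][2];
  if (tr > 0) {
    double s = std::sqrt(tr + 1.0) * 2;
    q[0] = 0.25 * s;
    q[1] = (R[2][1] - R[1][2]) / s;
    q[2] = (R[0][2] - R[2][0]) / s;
    q[3] = (R[1][0] - R[0][1]) / s;
  } else if (R[0][0] > R[1][1] && R[0][0] > R[2][2]) {
    double s = std::sqrt(1.0 + R[0][0] - R[1][1] - R[2][2]) * 2;
    q[0] = (R[2][1] - R[1][2]) / s; q[1] = 0.25 * s;
    q[2] = (R[0][1] + R[1][0]) / s; q[3] = (R[0][2] + R[2][0]) / s;
  } else if (R[1][1] > R[2][2]) {
    double s = std::sqrt(1.0 + R[1][1] - R[0][0] - R[2][2]) * 2;
    q[0] = (R[0][2] - R[2][0]) / s; q[1] = (R[0][1] + R[1][0]) / s;
    q[2] = 0.25 * s; q[3] = (R[1][2] + R[2][1]) / s;
  } else {
    double s = std::sqrt(1.0 + R[2][2] - R[0][0] - R[1][1]) * 2;
    q[0] = (R[1][0] - R[0][1]) / s; q[1] = (R[0][2] + R[2][0]) / s;
    q[2] = (R[1][2] + R[2][1]) / s; q[3] = 0.25 * s;
  }
}

// Exhaustive rigid-body grid scan: translations of the ligand centroid on a
// cubic grid (step t_step) clipped to a sphere of `radius` around `center`,
// crossed with a ZYZ Euler-angle rotation grid of step r_step_deg. Halving
// either step yields a superset of poses, so the minimum can only decrease.
// When return_table is false a clash early-exit is used for speed (clashed
// poses get an energy offset of +1e8, which cannot change the argmin since a
// clashed pose is hugely positive anyway); when true the exact energy of
// every pose is tabulated.
// [[Rcpp::export]]
List cpp_grid_scan(NumericMatrix px, NumericVector pq, NumericVector peps,
                   NumericVector prmin, NumericMatrix ltpl, NumericVector lq,
                   NumericVector leps, NumericVector lrmin, NumericVector center,
                   double radius, double t_step, double r_step_deg, double cutoff,
                   bool return_table = false,
                   Nullable<NumericMatrix> ref_rotation = R_NilValue,
                   double max_rot_angle_deg = 180.0) {
  PairTable t = build_table(px, pq, peps, prmin, lq, leps, lrmin, cutoff);
  int np = t.np, nl = t.nl;
  double rc2 = t.rc2;
  // template centroid and offsets
  double m0 = 0, m1 = 0, m2 = 0;
  for (int j = 0; j < nl; ++j) { m0 += ltpl(j, 0); m1 += ltpl(j, 1); m2 += ltpl(j, 2); }
  m0 /= nl; m1 /= nl; m2 /= nl;
  double rlig = 0.0;
  std::vector<double> off(3 * nl);
  for (int j = 0; j < nl; ++j) {
    off[3 * j] = ltpl(j, 0) - m0;
    off[3 * j + 1] = ltpl(j, 1) - m1;
    off[3 * j + 2] = ltpl(j, 2) - m2;
    double n2 = off[3 * j] * off[3 * j] + off[3 * j + 1] * off[3 * j + 1] +
                off[3 * j + 2] * off[3 * j + 2];
    if (n2 > rlig) rlig = n2;
  }
  rlig = std::sqrt(rlig);
  // rotation grid (ZYZ Euler)
  std::vector<double> rots; // 9 per rotation
  {
    double s = r_step_deg * M_PI / 180.0;
    int na = std::max(1, (int)std::round(2 * M_PI / s));
    int nb = (int)std::floor(M_PI / s + 1e-9) + 1;
    for (int ia = 0; ia < na; ++ia) {
      double A = ia * s;
      for (int ib = 0; ib < nb; ++ib) {
        double B = ib * s;
        for (int ig = 0; ig < na; ++ig) {
          double G = ig * s;
          double ca = std::cos(A), sa = std::sin(A), cb = std::cos(B),
                 sb = std::sin(B), cg = std::cos(G), sg = std::sin(G);
          // Rz(A)*Ry(B)*Rz(G)
          double R[9] = {ca * cb * cg - sa * sg, -ca * cb * sg - sa * cg, ca * sb,
                         sa * cb * cg + ca * sg, -sa * cb * sg + ca * cg, sa * sb,
                         -sb * cg, sb * sg, cb};
          for (int k = 0; k < 9; ++k) rots.push_back(R[k]);
        }
      }
    }
  }
  // optionally keep only rotations within max_rot_angle of a reference
  // orientation (used for local refinement scans around a known pose)
  if (ref_rotation.isNotNull() && max_rot_angle_deg < 180.0) {
    NumericMatrix Rf(ref_rotation);
    double cmin = std::cos(max_rot_angle_deg * M_PI / 180.0);
    std::vector<double> kept;
    for (size_t r = 0; r < rots.size() / 9; ++r) {
      const double *R = &rots[9 * r];
      // trace(Rf^T R) = 1 + 2 cos(angle between rotations)
      double tr = 0.0;
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) tr += Rf(a, b) * R[3 * a + b];
      if ((tr - 1.0) / 2.0 >= cmin) {
        for (int k = 0; k < 9; ++k) kept.push_back(R[k]);
      }
    }
    if (!kept.empty()) rots = kept;
  }
  int nrot = rots.size() / 9;
  // pre-rotate offsets for every rotation
  std::vector<double> roff((size_t)nrot * 3 * nl);
  for (int r = 0; r < nrot; ++r) {
    const double *R = &rots[9 * r];
    for (int j = 0; j < nl; ++j) {
      double ox = off[3 * j], oy = off[3 * j + 1], oz = off[3 * j + 2];
      roff[(size_t)r * 3 * nl + 3 * j] = R[0] * ox + R[1] * oy + R[2] * oz;
      roff[(size_t)r * 3 * nl + 3 * j + 1] = R[3] * ox + R[4] * oy + R[5] * oz;
      roff[(size_t)r * 3 * nl + 3 * j + 2] = R[6] * ox + R[7] * oy + R[8] * oz;
    }
  }
  int K = (int)std::floor(radius / t_step + 1e-9);
  double best = R_PosInf;
  double best_t[3] = {0, 0, 0};
  int best_r = 0;
  std::vector<double> table;
  long n_poses = 0;
  double reach = cutoff + rlig;
  double reach2 = reach * reach;
  std::vector<int> rel;
  rel.reserve(np);
  // scratch pair table restricted to the relevant protein atoms
  std::vector<double> rpx(3 * np), reps(t.eps.size()), rrmin2(t.eps.size()),
      rkqq(t.eps.size()), rshift(t.eps.size());
  for (int ix = -K; ix <= K; ++ix) {
    for (int iy = -K; iy <= K; ++iy) {
      for (int iz = -K; iz <= K; ++iz) {
        double tx = ix * t_step, ty = iy * t_step, tz = iz * t_step;
        if (tx * tx + ty * ty + tz * tz > radius * radius + 1e-9) continue;
        double cx = center[0] + tx, cy = center[1] + ty, cz = center[2] + tz;
        // protein atoms that can possibly be within cutoff of any ligand atom
        rel.clear();
        for (int i = 0; i < np; ++i) {
          double dx = t.px[3 * i] - cx, dy = t.px[3 * i + 1] - cy,
                 dz = t.px[3 * i + 2] - cz;
          if (dx * dx + dy * dy + dz * dz <= reach2) rel.push_back(i);
        }
        int nrel = rel.size();
        for (int ii = 0; ii < nrel; ++ii) {
          int i = rel[ii];
          rpx[3 * ii] = t.px[3 * i];
          rpx[3 * ii + 1] = t.px[3 * i + 1];
          rpx[3 * ii + 2] = t.px[3 * i + 2];
          size_t src = (size_t)i * nl, dst = (size_t)ii * nl;
          for (int j = 0; j < nl; ++j) {
            reps[dst + j] = t.eps[src + j];
            rrmin2[dst + j] = t.rmin2[src + j];
            rkqq[dst + j] = t.kqq[src + j];
            rshift[dst + j] = t.shift[src + j];
          }
        }
        for (int r = 0; r < nrot; ++r) {
          const double *RO = &roff[(size_t)r * 3 * nl];
          double etot = 0.0;
          bool clash = false;
          for (int j = 0; j < nl && !clash; ++j) {
            double xj = cx + RO[3 * j], yj = cy + RO[3 * j + 1], zj = cz + RO[3 * j + 2];
            for (int ii = 0; ii < nrel; ++ii) {
              double dx = xj - rpx[3 * ii], dy = yj - rpx[3 * ii + 1],
                     dz = zj - rpx[3 * ii + 2];
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 >= rc2) continue;
              size_t k = (size_t)ii * nl + j;
              if (!return_table && r2 < 0.3 * rrmin2[k]) {
                etot += 1e8;
                clash = true;
                break;
              }
              double inv = 1.0 / r2;
              double a = rrmin2[k] * inv;
              double a3 = a * a * a;
              etot += reps[k] * (a3 * a3 - 2.0 * a3) + rkqq[k] * inv - rshift[k];
            }
          }
          ++n_poses;
          if (etot < best) {
            best = etot;
            best_t[0] = tx; best_t[1] = ty; best_t[2] = tz;
            best_r = r;
          }
          if (return_table) {
            double Rm[3][3] = {{rots[9 * r], rots[9 * r + 1], rots[9 * r + 2]},
                               {rots[9 * r + 3], rots[9 * r + 4], rots[9 * r + 5]},
                               {rots[9 * r + 6], rots[9 * r + 7], rots[9 * r + 8]}};
            double q[4];
            mat_to_quat(Rm, q);
            table.push_back(tx); table.push_back(ty); table.push_back(tz);
            table.push_back(q[0]); table.push_back(q[1]); table.push_back(q[2]);
            table.push_back(q[3]); table.push_back(etot);
          }
        }
      }
    }
  }
  double Rb[3][3] = {{rots[9 * best_r], rots[9 * best_r + 1], rots[9 * best_r + 2]},
                     {rots[9 * best_r + 3], rots[9 * best_r + 4], rots[9 * best_r + 5]},
                     {rots[9 * best_r + 6], rots[9 * best_r + 7], rots[9 * best_r + 8]}};
  double qb[4];
  mat_to_quat(Rb, qb);
  NumericMatrix rot(3, 3);
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) rot(a, b) = Rb[a][b];
  List out = List::create(
      _["best_energy"] = best,
      _["best_translation"] = NumericVector::create(best_t[0], best_t[1], best_t[2]),
      _["best_rotation"] = rot,
      _["best_quaternion"] = NumericVector::create(qb[0], qb[1], qb[2], qb[3]),
      _["n_poses"] = (double)n_poses);
  if (return_table) {
    int nr = table.size() / 8;
    NumericMatrix tb(nr, 8);
    for (int i = 0; i < nr; ++i)
      for (int k = 0; k < 8; ++k) tb(i, k) = table[(size_t)i * 8 + k];
    colnames(tb) = CharacterVector::create("tx", "ty", "tz", "qw", "qx", "qy",
                                           "qz", "energy");
    out["table"] = tb;
  }
  return out;
}
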
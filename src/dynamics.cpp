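// Inner loops of the toy dynamics engine: potential energy + analytic forces
// and a BAOAB-discretised Langevin propagator with optional half-harmonic
// walls on centre-of-mass distance reaction coordinates.
//
// Units: lengths in Angstrom, energies in kcal/mol, masses in amu, time in fs.
// Noise is drawn from R's RNG (norm_rand), so set.seed() in R governs every
// stochastic choice made here.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// (kcal/mol/A) / amu -> A/fs^2
static const double KCAL_PER_AMU = 4.184e-4;
// Minimum nonbonded separation before we declare a bead overlap.
static const double R_FLOOR = 1e-6;

struct WallSpec {
  std::vector<int> ia, ib;      // 0-based bead indices of the two groups
  std::vector<double> wa, wb;   // normalised centre weights
  double lo, hi, k;             // active window and wall stiffness
};

// lambda = |cA - cB| for one wall spec; also returns the unit vector and centres
static double wall_lambda(const std::vector<double>& x, const WallSpec& w,
                          double* u /* length 3 */) {
  double ca[3] = {0, 0, 0}, cb[3] = {0, 0, 0};
  for (size_t m = 0; m < w.ia.size(); ++m)
    for (int d = 0; d < 3; ++d) ca[d] += w.wa[m] * x[3 * w.ia[m] + d];
  for (size_t m = 0; m < w.ib.size(); ++m)
    for (int d = 0; d < 3; ++d) cb[d] += w.wb[m] * x[3 * w.ib[m] + d];
  double dx = ca[0] - cb[0], dy = ca[1] - cb[1], dz = ca[2] - cb[2];
  double r = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (r < 1e-12) r = 1e-12;
  u[0] = dx / r; u[1] = dy / r; u[2] = dz / r;
  return r;
}

struct Topology {
  int n;
  std::vector<int> b_i, b_j;              std::vector<double> b_k, b_r0;
  std::vector<int> a_i, a_j, a_k;         std::vector<double> a_ka, a_t0;
  std::vector<int> p_i, p_j;              std::vector<double> p_eps, p_sig;
  std::vector<int> r_idx;                 std::vector<double> r_x, r_y, r_z, r_k;
  std::vector<WallSpec> walls;
};

static Topology unpack(int n, const IntegerMatrix& bonds, const NumericMatrix& bpar,
                       const IntegerMatrix& angles, const NumericMatrix& apar,
                       const IntegerMatrix& pairs, const NumericMatrix& ppar,
                       const IntegerVector& rest_idx, const NumericMatrix& rest_anchor,
                       const NumericVector& rest_k, const List& walls) {
  Topology t; t.n = n;
  for (int m = 0; m < bonds.nrow(); ++m) {
    t.b_i.push_back(bonds(m, 0) - 1); t.b_j.push_back(bonds(m, 1) - 1);
    t.b_k.push_back(bpar(m, 0)); t.b_r0.push_back(bpar(m, 1));
  }
  for (int m = 0; m < angles.nrow(); ++m) {
    t.a_i.push_back(angles(m, 0) - 1); t.a_j.push_back(angles(m, 1) - 1);
    t.a_k.push_back(angles(m, 2) - 1);
    t.a_ka.push_back(apar(m, 0)); t.a_t0.push_back(apar(m, 1));
  }
  for (int m = 0; m < pairs.nrow(); ++m) {
    t.p_i.push_back(pairs(m, 0) - 1); t.p_j.push_back(pairs(m, 1) - 1);
    t.p_eps.push_back(ppar(m, 0)); t.p_sig.push_back(ppar(m, 1));
  }
  for (int m = 0; m < rest_idx.size(); ++m) {
    t.r_idx.push_back(rest_idx[m] - 1);
    t.r_x.push_back(rest_anchor(m, 0)); t.r_y.push_back(rest_anchor(m, 1));
    t.r_z.push_back(rest_anchor(m, 2)); t.r_k.push_back(rest_k[m]);
  }
  for (int w = 0; w < walls.size(); ++w) {
    List ws = walls[w];
    WallSpec s;
    IntegerVector ia = ws["ia"], ib = ws["ib"];
    NumericVector wa = ws["wa"], wb = ws["wb"];
    for (int m = 0; m < ia.size(); ++m) { s.ia.push_back(ia[m] - 1); s.wa.push_back(wa[m]); }
    for (int m = 0; m < ib.size(); ++m) { s.ib.push_back(ib[m] - 1); s.wb.push_back(wb[m]); }
    s.lo = as<double>(ws["lo"]); s.hi = as<double>(ws["hi"]); s.k = as<double>(ws["k"]);
    t.walls.push_back(s);
  }
  return t;
}

// E = sum k_b (r-r0)^2 + sum k_a (theta-theta0)^2 + sum 4 eps [(s/r)^12-(s/r)^6]
//   + sum k_r |x - x_ref|^2 + half-harmonic walls; F = -grad E
static double energy_forces(const std::vector<double>& x, const Topology& t,
                            std::vector<double>& f) {
  std::fill(f.begin(), f.end(), 0.0);
  double e = 0.0;

  for (size_t m = 0; m < t.b_i.size(); ++m) {
    int i = t.b_i[m], j = t.b_j[m];
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) r = 1e-12;
    double dr = r - t.b_r0[m];
    e += t.b_k[m] * dr * dr;
    double c = -2.0 * t.b_k[m] * dr / r;
    f[3 * i] += c * dx; f[3 * i + 1] += c * dy; f[3 * i + 2] += c * dz;
    f[3 * j] -= c * dx; f[3 * j + 1] -= c * dy; f[3 * j + 2] -= c * dz;
  }

  for (size_t m = 0; m < t.a_i.size(); ++m) {
    int i = t.a_i[m], j = t.a_j[m], k = t.a_k[m];
    double rij[3], rkj[3];
    for (int d = 0; d < 3; ++d) {
      rij[d] = x[3 * i + d] - x[3 * j + d];
      rkj[d] = x[3 * k + d] - x[3 * j + d];
    }
    double nij = std::sqrt(rij[0] * rij[0] + rij[1] * rij[1] + rij[2] * rij[2]);
    double nkj = std::sqrt(rkj[0] * rkj[0] + rkj[1] * rkj[1] + rkj[2] * rkj[2]);
    if (nij < 1e-12 || nkj < 1e-12) continue;
    double cs = (rij[0] * rkj[0] + rij[1] * rkj[1] + rij[2] * rkj[2]) / (nij * nkj);
    if (cs > 1.0) cs = 1.0; if (cs < -1.0) cs = -1.0;
    double th = std::acos(cs);
    double dth = th - t.a_t0[m];
    e += t.a_ka[m] * dth * dth;
    double sn = std::sqrt(1.0 - cs * cs);
    if (sn < 1e-8) sn = 1e-8;             // near-linear angle: bounded force
    double dEdth = 2.0 * t.a_ka[m] * dth;
    double c1 = dEdth / (sn * nij), c2 = dEdth / (sn * nkj);
    for (int d = 0; d < 3; ++d) {
      double gi = c1 * (rkj[d] / nkj - cs * rij[d] / nij);
      double gk = c2 * (rij[d] / nij - cs * rkj[d] / nkj);
      f[3 * i + d] += gi;
      f[3 * k + d] += gk;
      f[3 * j + d] -= gi + gk;
    }
  }

  for (size_t m = 0; m < t.p_i.size(); ++m) {
    int i = t.p_i[m], j = t.p_j[m];
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    double r = std::sqrt(r2);
    if (r < R_FLOOR)
      stop("bead overlap: nonbonded pair (%d, %d) at separation %g A", i + 1, j + 1, r);
    double sr2 = (t.p_sig[m] * t.p_sig[m]) / r2;
    double sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
    e += 4.0 * t.p_eps[m] * (sr12 - sr6);
    double c = 24.0 * t.p_eps[m] * (2.0 * sr12 - sr6) / r2;
    f[3 * i] += c * dx; f[3 * i + 1] += c * dy; f[3 * i + 2] += c * dz;
    f[3 * j] -= c * dx; f[3 * j + 1] -= c * dy; f[3 * j + 2] -= c * dz;
  }

  for (size_t m = 0; m < t.r_idx.size(); ++m) {
    int i = t.r_idx[m];
    double dx = x[3 * i] - t.r_x[m], dy = x[3 * i + 1] - t.r_y[m],
           dz = x[3 * i + 2] - t.r_z[m];
    e += t.r_k[m] * (dx * dx + dy * dy + dz * dz);
    f[3 * i] -= 2.0 * t.r_k[m] * dx;
    f[3 * i + 1] -= 2.0 * t.r_k[m] * dy;
    f[3 * i + 2] -= 2.0 * t.r_k[m] * dz;
  }

  for (size_t w = 0; w < t.walls.size(); ++w) {
    const WallSpec& s = t.walls[w];
    double u[3];
    double lam = wall_lambda(x, s, u);
    double dEdl = 0.0;
    if (lam > s.hi) { double d = lam - s.hi; e += s.k * d * d; dEdl = 2.0 * s.k * d; }
    else if (lam < s.lo) { double d = s.lo - lam; e += s.k * d * d; dEdl = -2.0 * s.k * d; }
    if (dEdl != 0.0) {
      for (size_t m = 0; m < s.ia.size(); ++m)
        for (int d = 0; d < 3; ++d) f[3 * s.ia[m] + d] -= dEdl * s.wa[m] * u[d];
      for (size_t m = 0; m < s.ib.size(); ++m)
        for (int d = 0; d < 3; ++d) f[3 * s.ib[m] + d] += dEdl * s.wb[m] * u[d];
    }
  }
  return e;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix coords,
                       IntegerMatrix bonds, NumericMatrix bpar,
                       IntegerMatrix angles, NumericMatrix apar,
                       IntegerMatrix pairs, NumericMatrix ppar,
                       IntegerVector rest_idx, NumericMatrix rest_anchor,
                       NumericVector rest_k, List walls) {
  int n = coords.nrow();
  Topology t = unpack(n, bonds, bpar, angles, apar, pairs, ppar,
                      rest_idx, rest_anchor, rest_k, walls);
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  double e = energy_forces(x, t, f);
  NumericMatrix fm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) fm(i, d) = f[3 * i + d];
  return List::create(_["energy"] = e, _["forces"] = fm);
}

// [[Rcpp::export]]
List cpp_baoab(NumericMatrix coords, NumericMatrix vels, NumericVector masses,
               int n_steps, double dt, double gamma_fs, double kT,
               int snapshot_interval,
               IntegerMatrix bonds, NumericMatrix bpar,
               IntegerMatrix angles, NumericMatrix apar,
               IntegerMatrix pairs, NumericMatrix ppar,
               IntegerVector rest_idx, NumericMatrix rest_anchor,
               NumericVector rest_k, List walls) {
  int n = coords.nrow();
  Topology t = unpack(n, bonds, bpar, angles, apar, pairs, ppar,
                      rest_idx, rest_anchor, rest_k, walls);
  std::vector<double> x(3 * n), v(3 * n), f(3 * n), minv(n), sig(n);
  for (int i = 0; i < n; ++i) {
    double mprog = masses[i] / KCAL_PER_AMU;  // amu -> program mass units
    minv[i] = 1.0 / mprog;
    sig[i] = std::sqrt(kT / mprog);           // thermal velocity scale, A/fs
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = coords(i, d);
      v[3 * i + d] = vels(i, d);
    }
  }
  double c1 = std::exp(-gamma_fs * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);

  int n_snap = (snapshot_interval > 0) ? n_steps / snapshot_interval : 0;
  NumericMatrix snaps(n_snap * n, 3);
  IntegerVector snap_steps(n_snap);
  int isnap = 0;

  double e = energy_forces(x, t, f);
  for (int step = 1; step <= n_steps; ++step) {
    double hdt = 0.5 * dt;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v[3 * i + d] += hdt * f[3 * i + d] * minv[i];
    for (int i = 0; i < 3 * n; ++i) x[i] += hdt * v[i];
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        v[3 * i + d] = c1 * v[3 * i + d] + c2 * sig[i] * norm_rand();
    for (int i = 0; i < 3 * n; ++i) x[i] += hdt * v[i];
    e = energy_forces(x, t, f);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) v[3 * i + d] += hdt * f[3 * i + d] * minv[i];

    if (!std::isfinite(e))
      stop("integration failure: non-finite energy at step %d", step);

    if (snapshot_interval > 0 && step % snapshot_interval == 0) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) snaps(isnap * n + i, d) = x[3 * i + d];
      snap_steps[isnap] = step;
      ++isnap;
    }
  }

  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      xf(i, d) = x[3 * i + d];
      vf(i, d) = v[3 * i + d];
    }
  return List::create(_["snapshots"] = snaps, _["snap_steps"] = snap_steps,
                      _["coords"] = xf, _["vels"] = vf, _["energy"] = e);
}
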
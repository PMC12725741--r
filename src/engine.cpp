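// Core numerics: Lennard-Jones/WCA force field with cell-list neighbor
// search, harmonic bonds, (1 - cos theta) bending, BAOAB Langevin
// integration with fixed tether particles, brute-force k-NN distances and
// DBSCAN with an optional periodic minimum-image metric.
//
// Conventions: reduced units (kBT = 1, sigma = 1, m = 1). Positions are kept
// unwrapped; all pair distances use the minimum image, so coordinates may
// lie outside the primary box. Directly bonded pairs are excluded from
// nonbonded interactions (1-2 exclusion). Attractive pairs with eps <= 0 do
// not interact at all.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double LJ_CUT = 2.5;
static const double WCA_CUT = 1.122462048309373; // 2^(1/6)

// shifted 12-6 LJ, zero at cutoff rc; returns energy, sets f_over_r
static inline double lj_shifted(double r2, double eps, double rc,
                                double &f_over_r) {
  double rc2 = rc * rc;
  if (r2 >= rc2 || eps <= 0.0) { f_over_r = 0.0; return 0.0; }
  double inv2 = 1.0 / r2;
  double inv6 = inv2 * inv2 * inv2;
  double inv12 = inv6 * inv6;
  double irc6 = 1.0 / (rc2 * rc2 * rc2);
  double shift = 4.0 * eps * (irc6 * irc6 - irc6);
  double e = 4.0 * eps * (inv12 - inv6) - shift;
  f_over_r = 24.0 * eps * (2.0 * inv12 - inv6) * inv2; // F = f_over_r * dr
  return e;
}

struct PairParams {
  // per-particle: kind >= 0 -> monomer (index into eps_mp), kind == -1 ->
  // protein
  const int *kind;
  const double *eps_mp;
  double eps_pp;
};

// energy and force factor for a nonbonded pair
static inline double pair_ef(int ki, int kj, const PairParams &pp, double r2,
                             double &f_over_r) {
  if (ki >= 0 && kj >= 0) {
    // monomer-monomer: WCA (LJ eps = 1 truncated at minimum, shifted)
    return lj_shifted(r2, 1.0, WCA_CUT, f_over_r);
  }
  double eps = (ki < 0 && kj < 0) ? pp.eps_pp
                                  : pp.eps_mp[ki >= 0 ? ki : kj];
  return lj_shifted(r2, eps, LJ_CUT, f_over_r);
}

static inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// valid when both coordinates lie in [0, L): |d| < L
static inline double min_image_wrapped(double d, double L) {
  if (d > 0.5 * L) return d - L;
  if (d < -0.5 * L) return d + L;
  return d;
}

static inline double wrap01(double x, double L) {
  double f = x / L - std::floor(x / L);
  return f * L;
}

class CellList {
public:
  int ncx, ncy, ncz;
  double Lx, Ly, Lz;
  std::vector<std::vector<int>> cells;
  std::vector<int> occupied;
  bool use_cells;

  CellList(const NumericVector &box, double cutoff, int n) {
    Lx = box[0]; Ly = box[1]; Lz = box[2];
    ncx = std::max(1, (int)std::floor(Lx / cutoff));
    ncy = std::max(1, (int)std::floor(Ly / cutoff));
    ncz = std::max(1, (int)std::floor(Lz / cutoff));
    // with fewer than 3 cells along an axis neighbor shells overlap; fall
    // back to all-pairs; also cap the cell count for very dilute systems
    double ncells = (double)ncx * ncy * ncz;
    use_cells = (ncx >= 3 && ncy >= 3 && ncz >= 3 && n > 64 &&
                 ncells <= 1e6 && ncells <= 100.0 * n);
    if (use_cells) cells.resize((size_t)ncx * ncy * ncz);
  }

  static inline int wrap_bin(double x, double L, int nc) {
    double frac = x / L - std::floor(x / L);
    int b = (int)(frac * nc);
    if (b >= nc) b = nc - 1;
    return b;
  }

  inline int bin(double x, double y, double z) const {
    int ix = wrap_bin(x, Lx, ncx), iy = wrap_bin(y, Ly, ncy),
        iz = wrap_bin(z, Lz, ncz);
    return (ix * ncy + iy) * ncz + iz;
  }

  void build(const std::vector<double> &px, const std::vector<double> &py,
             const std::vector<double> &pz) {
    for (int c : occupied) cells[c].clear();
    occupied.clear();
    for (size_t i = 0; i < px.size(); ++i) {
      int b = bin(px[i], py[i], pz[i]);
      if (cells[b].empty()) occupied.push_back(b);
      cells[b].push_back((int)i);
    }
  }
};

struct System {
  int n;
  std::vector<double> px, py, pz, vx, vy, vz, fx, fy, fz;
  std::vector<int> kind;       // >=0 monomer kind index, -1 protein
  std::vector<char> fixed_;
  std::vector<std::vector<int>> excl; // 1-2 exclusions
  IntegerMatrix bonds;   // nb x 2 (0-based)
  IntegerMatrix angles;  // na x 3 (0-based)
  NumericVector box;
  double kb, l0, kappa, eps_pp;
  std::vector<double> eps_mp;
  bool has_nonbonded;
  bool wrapped = false; // positions guaranteed in [0, L)
};

static double compute_forces(System &S, CellList &cl) {
  const double Lx = S.box[0], Ly = S.box[1], Lz = S.box[2];
  std::fill(S.fx.begin(), S.fx.end(), 0.0);
  std::fill(S.fy.begin(), S.fy.end(), 0.0);
  std::fill(S.fz.begin(), S.fz.end(), 0.0);
  double energy = 0.0;
  PairParams pp{S.kind.data(), S.eps_mp.data(), S.eps_pp};

  const bool wr = S.wrapped;
  auto do_pair = [&](int i, int j) {
    // 1-2 exclusion
    for (int e : S.excl[i]) if (e == j) return;
    double dx = wr ? min_image_wrapped(S.px[i] - S.px[j], Lx)
                   : min_image(S.px[i] - S.px[j], Lx);
    double dy = wr ? min_image_wrapped(S.py[i] - S.py[j], Ly)
                   : min_image(S.py[i] - S.py[j], Ly);
    double dz = wr ? min_image_wrapped(S.pz[i] - S.pz[j], Lz)
                   : min_image(S.pz[i] - S.pz[j], Lz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= LJ_CUT * LJ_CUT) return;
    double fr;
    energy += pair_ef(S.kind[i], S.kind[j], pp, r2, fr);
    S.fx[i] += fr * dx; S.fy[i] += fr * dy; S.fz[i] += fr * dz;
    S.fx[j] -= fr * dx; S.fy[j] -= fr * dy; S.fz[j] -= fr * dz;
  };

  if (!S.has_nonbonded) {
    // ideal gas of attractive particles with eps <= 0: no pair terms
  } else if (cl.use_cells) {
    cl.build(S.px, S.py, S.pz);
    for (int c : cl.occupied) {
      const auto &ci = cl.cells[c];
      int cx = c / (cl.ncy * cl.ncz);
      int cy = (c / cl.ncz) % cl.ncy;
      int cz = c % cl.ncz;
      for (int ox = -1; ox <= 1; ++ox)
        for (int oy = -1; oy <= 1; ++oy)
          for (int oz = -1; oz <= 1; ++oz) {
            int nx = (cx + ox + cl.ncx) % cl.ncx;
            int ny = (cy + oy + cl.ncy) % cl.ncy;
            int nz = (cz + oz + cl.ncz) % cl.ncz;
            int c2 = (nx * cl.ncy + ny) * cl.ncz + nz;
            if (c2 < c) continue; // each cell pair once
            const auto &cj = cl.cells[c2];
            if (cj.empty()) continue;
            if (c2 == c) {
              for (size_t a = 0; a < ci.size(); ++a)
                for (size_t b = a + 1; b < ci.size(); ++b)
                  do_pair(ci[a], ci[b]);
            } else {
              for (int i : ci)
                for (int j : cj) do_pair(i, j);
            }
          }
    }
  } else {
    for (int i = 0; i < S.n; ++i)
      for (int j = i + 1; j < S.n; ++j) do_pair(i, j);
  }

  // harmonic bonds
  for (int b = 0; b < S.bonds.nrow(); ++b) {
    int i = S.bonds(b, 0), j = S.bonds(b, 1);
    double dx = min_image(S.px[i] - S.px[j], Lx);
    double dy = min_image(S.py[i] - S.py[j], Ly);
    double dz = min_image(S.pz[i] - S.pz[j], Lz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r <= 0.0) stop("zero bond length encountered");
    double d = r - S.l0;
    energy += 0.5 * S.kb * d * d;
    double fmag = -S.kb * d / r; // along dr = ri - rj
    S.fx[i] += fmag * dx; S.fy[i] += fmag * dy; S.fz[i] += fmag * dz;
    S.fx[j] -= fmag * dx; S.fy[j] -= fmag * dy; S.fz[j] -= fmag * dz;
  }

  // bending: E = kappa * (1 - cos theta), theta between consecutive bond
  // vectors b1 = r2 - r1, b2 = r3 - r2
  for (int a = 0; a < S.angles.nrow(); ++a) {
    int i = S.angles(a, 0), j = S.angles(a, 1), k = S.angles(a, 2);
    double b1x = min_image(S.px[j] - S.px[i], Lx);
    double b1y = min_image(S.py[j] - S.py[i], Ly);
    double b1z = min_image(S.pz[j] - S.pz[i], Lz);
    double b2x = min_image(S.px[k] - S.px[j], Lx);
    double b2y = min_image(S.py[k] - S.py[j], Ly);
    double b2z = min_image(S.pz[k] - S.pz[j], Lz);
    double n1 = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
    double n2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    double dot = b1x * b2x + b1y * b2y + b1z * b2z;
    double c = dot / (n1 * n2);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    energy += S.kappa * (1.0 - c);
    // dE/d(cos) = -kappa; F = -dE/dr = kappa * d(cos)/dr
    double inv12 = 1.0 / (n1 * n2);
    double g1x = b2x * inv12 - c * b1x / (n1 * n1); // d cos / d b1
    double g1y = b2y * inv12 - c * b1y / (n1 * n1);
    double g1z = b2z * inv12 - c * b1z / (n1 * n1);
    double g2x = b1x * inv12 - c * b2x / (n2 * n2); // d cos / d b2
    double g2y = b1y * inv12 - c * b2y / (n2 * n2);
    double g2z = b1z * inv12 - c * b2z / (n2 * n2);
    // b1 depends on r_i (-1) and r_j (+1); b2 on r_j (-1), r_k (+1)
    S.fx[i] += S.kappa * (-g1x); S.fy[i] += S.kappa * (-g1y);
    S.fz[i] += S.kappa * (-g1z);
    S.fx[j] += S.kappa * (g1x - g2x); S.fy[j] += S.kappa * (g1y - g2y);
    S.fz[j] += S.kappa * (g1z - g2z);
    S.fx[k] += S.kappa * (g2x); S.fy[k] += S.kappa * (g2y);
    S.fz[k] += S.kappa * (g2z);
  }

  return energy;
}

static System make_system(NumericMatrix pos, NumericMatrix vel,
                          IntegerVector kind, NumericVector eps_mp,
                          double eps_pp, IntegerMatrix bonds,
                          IntegerMatrix angles, IntegerVector tethered,
                          NumericVector box, double kb, double l0,
                          double kappa) {
  System S;
  S.n = pos.nrow();
  if (vel.nrow() != S.n) stop("pos/vel shape mismatch");
  S.px.resize(S.n); S.py.resize(S.n); S.pz.resize(S.n);
  S.vx.resize(S.n); S.vy.resize(S.n); S.vz.resize(S.n);
  S.fx.resize(S.n); S.fy.resize(S.n); S.fz.resize(S.n);
  S.kind.resize(S.n);
  S.fixed_.assign(S.n, 0);
  S.excl.assign(S.n, {});
  for (int i = 0; i < S.n; ++i) {
    S.px[i] = pos(i, 0); S.py[i] = pos(i, 1); S.pz[i] = pos(i, 2);
    S.vx[i] = vel(i, 0); S.vy[i] = vel(i, 1); S.vz[i] = vel(i, 2);
    S.kind[i] = kind[i];
  }
  for (int t = 0; t < tethered.size(); ++t) {
    int i = tethered[t];
    if (i < 0 || i >= S.n) stop("tethered index out of range");
    S.fixed_[i] = 1;
  }
  for (int b = 0; b < bonds.nrow(); ++b) {
    S.excl[bonds(b, 0)].push_back(bonds(b, 1));
    S.excl[bonds(b, 1)].push_back(bonds(b, 0));
  }
  S.bonds = bonds; S.angles = angles; S.box = box;
  S.kb = kb; S.l0 = l0; S.kappa = kappa; S.eps_pp = eps_pp;
  S.eps_mp.assign(eps_mp.begin(), eps_mp.end());
  bool any_monomer = false;
  for (int i = 0; i < S.n; ++i) if (S.kind[i] >= 0) any_monomer = true;
  S.has_nonbonded = any_monomer || eps_pp > 0.0;
  return S;
}

// [[Rcpp::export]]
List cpp_forces_energy(NumericMatrix pos, IntegerVector kind,
                       NumericVector eps_mp, double eps_pp,
                       IntegerMatrix bonds, IntegerMatrix angles,
                       NumericVector box, double kb, double l0,
                       double kappa) {
  NumericMatrix vel(pos.nrow(), 3);
  System S = make_system(pos, vel, kind, eps_mp, eps_pp, bonds, angles,
                         IntegerVector(0), box, kb, l0, kappa);
  CellList cl(box, LJ_CUT, S.n);
  double e = compute_forces(S, cl);
  NumericMatrix f(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    f(i, 0) = S.fx[i]; f(i, 1) = S.fy[i]; f(i, 2) = S.fz[i];
  }
  return List::create(_["energy"] = e, _["forces"] = f);
}

// [[Rcpp::export]]
List cpp_run_bd(NumericMatrix pos, NumericMatrix vel, IntegerVector kind,
                NumericVector eps_mp, double eps_pp, IntegerMatrix bonds,
                IntegerMatrix angles, IntegerVector tethered,
                NumericVector box, double kb, double l0, double kappa,
                double dt, double gamma, double temperature,
                double nsteps_d, double save_every_d, int seed,
                bool overdamped) {
  long long nsteps = (long long)nsteps_d;
  long long save_every = (long long)save_every_d;
  System S = make_system(pos, vel, kind, eps_mp, eps_pp, bonds, angles,
                         tethered, box, kb, l0, kappa);
  CellList cl(box, LJ_CUT, S.n);

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(std::max(0.0, temperature * (1.0 - c1 * c1)));
  const double od_mob = dt / gamma;
  const double od_noise = std::sqrt(2.0 * temperature * dt / gamma);

  // with nonbonded interactions active, keep coordinates wrapped into the
  // primary box so pair separations use the cheap single-correction
  // minimum image; ideal-gas runs stay unwrapped (diffusion analysis)
  S.wrapped = S.has_nonbonded;
  auto wrap_all = [&]() {
    if (!S.wrapped) return;
    for (int i = 0; i < S.n; ++i) {
      if (S.fixed_[i]) continue; // anchors stay bit-identical
      S.px[i] = wrap01(S.px[i], box[0]);
      S.py[i] = wrap01(S.py[i], box[1]);
      S.pz[i] = wrap01(S.pz[i], box[2]);
    }
  };
  wrap_all();

  int nframes = save_every > 0 ? (int)(nsteps / save_every) : 0;
  NumericVector frames(nframes > 0 ? (R_xlen_t)S.n * 3 * nframes : 0);
  NumericVector frame_pe(nframes);
  NumericVector frame_steps(nframes);

  double energy = compute_forces(S, cl);
  int iframe = 0;

  for (long long step = 1; step <= nsteps; ++step) {
    if (overdamped) {
      for (int i = 0; i < S.n; ++i) {
        if (S.fixed_[i]) continue;
        S.px[i] += od_mob * S.fx[i] + od_noise * gauss(rng);
        S.py[i] += od_mob * S.fy[i] + od_noise * gauss(rng);
        S.pz[i] += od_mob * S.fz[i] + od_noise * gauss(rng);
      }
      wrap_all();
      energy = compute_forces(S, cl);
    } else {
      // BAOAB
      for (int i = 0; i < S.n; ++i) {
        if (S.fixed_[i]) continue;
        S.vx[i] += 0.5 * dt * S.fx[i];
        S.vy[i] += 0.5 * dt * S.fy[i];
        S.vz[i] += 0.5 * dt * S.fz[i];
        S.px[i] += 0.5 * dt * S.vx[i];
        S.py[i] += 0.5 * dt * S.vy[i];
        S.pz[i] += 0.5 * dt * S.vz[i];
        S.vx[i] = c1 * S.vx[i] + c2 * gauss(rng);
        S.vy[i] = c1 * S.vy[i] + c2 * gauss(rng);
        S.vz[i] = c1 * S.vz[i] + c2 * gauss(rng);
        S.px[i] += 0.5 * dt * S.vx[i];
        S.py[i] += 0.5 * dt * S.vy[i];
        S.pz[i] += 0.5 * dt * S.vz[i];
      }
      wrap_all();
      energy = compute_forces(S, cl);
      for (int i = 0; i < S.n; ++i) {
        if (S.fixed_[i]) continue;
        S.vx[i] += 0.5 * dt * S.fx[i];
        S.vy[i] += 0.5 * dt * S.fy[i];
        S.vz[i] += 0.5 * dt * S.fz[i];
      }
    }

    if (step % 10000 == 0) {
      for (int i = 0; i < S.n; ++i)
        if (!std::isfinite(S.px[i]) || !std::isfinite(S.py[i]) ||
            !std::isfinite(S.pz[i]))
          stop("non-finite coordinates at step %lld (particle %d)", step,
               i + 1);
      Rcpp::checkUserInterrupt();
    }

    if (save_every > 0 && step % save_every == 0 && iframe < nframes) {
      double *fr = frames.begin() + (R_xlen_t)iframe * S.n * 3;
      for (int i = 0; i < S.n; ++i) {
        fr[i] = S.px[i];
        fr[S.n + i] = S.py[i];
        fr[2 * S.n + i] = S.pz[i];
      }
      frame_pe[iframe] = energy;
      frame_steps[iframe] = (double)step;
      ++iframe;
    }
  }

  NumericMatrix pos_out(S.n, 3), vel_out(S.n, 3);
  double ke = 0.0;
  for (int i = 0; i < S.n; ++i) {
    pos_out(i, 0) = S.px[i]; pos_out(i, 1) = S.py[i];
    pos_out(i, 2) = S.pz[i];
    vel_out(i, 0) = S.vx[i]; vel_out(i, 1) = S.vy[i];
    vel_out(i, 2) = S.vz[i];
    if (!S.fixed_[i])
      ke += 0.5 * (S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] +
                   S.vz[i] * S.vz[i]);
  }
  if (nframes > 0) frames.attr("dim") = IntegerVector::create(S.n, 3, nframes);
  return List::create(_["positions"] = pos_out, _["velocities"] = vel_out,
                      _["frames"] = frames, _["frame_pe"] = frame_pe,
                      _["frame_steps"] = frame_steps,
                      _["potential_energy"] = energy,
                      _["kinetic_energy"] = ke);
}

// ---- per-monomer nonbonded energy shares ---------------------------------

// Each nonbonded pair's energy is split half/half between its partners;
// bonded (harmonic + bending) terms are likewise half-shared among the
// particles of the bond/angle. Returns the per-particle share vector.
// [[Rcpp::export]]
NumericVector cpp_energy_shares(NumericMatrix pos, IntegerVector kind,
                                NumericVector eps_mp, double eps_pp,
                                IntegerMatrix bonds, IntegerMatrix angles,
                                NumericVector box, double kb, double l0,
                                double kappa) {
  int n = pos.nrow();
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  NumericVector shares(n);
  PairParams pp{kind.begin(), eps_mp.begin(), eps_pp};
  std::vector<std::vector<int>> excl(n);
  for (int b = 0; b < bonds.nrow(); ++b) {
    excl[bonds(b, 0)].push_back(bonds(b, 1));
    excl[bonds(b, 1)].push_back(bonds(b, 0));
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      bool skip = false;
      for (int e : excl[i]) if (e == j) { skip = true; break; }
      if (skip) continue;
      double dx = min_image(pos(i, 0) - pos(j, 0), Lx);
      double dy = min_image(pos(i, 1) - pos(j, 1), Ly);
      double dz = min_image(pos(i, 2) - pos(j, 2), Lz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= LJ_CUT * LJ_CUT) continue;
      double fr;
      double e = pair_ef(kind[i], kind[j], pp, r2, fr);
      shares[i] += 0.5 * e;
      shares[j] += 0.5 * e;
    }
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = min_image(pos(i, 0) - pos(j, 0), Lx);
    double dy = min_image(pos(i, 1) - pos(j, 1), Ly);
    double dz = min_image(pos(i, 2) - pos(j, 2), Lz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double e = 0.5 * kb * (r - l0) * (r - l0);
    shares[i] += 0.5 * e;
    shares[j] += 0.5 * e;
  }
  for (int a = 0; a < angles.nrow(); ++a) {
    int i = angles(a, 0), j = angles(a, 1), k = angles(a, 2);
    double b1x = min_image(pos(j, 0) - pos(i, 0), Lx);
    double b1y = min_image(pos(j, 1) - pos(i, 1), Ly);
    double b1z = min_image(pos(j, 2) - pos(i, 2), Lz);
    double b2x = min_image(pos(k, 0) - pos(j, 0), Lx);
    double b2y = min_image(pos(k, 1) - pos(j, 1), Ly);
    double b2z = min_image(pos(k, 2) - pos(j, 2), Lz);
    double n1 = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
    double n2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    double c = (b1x * b2x + b1y * b2y + b1z * b2z) / (n1 * n2);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double e = kappa * (1.0 - c) / 3.0;
    shares[i] += e; shares[j] += e; shares[k] += e;
  }
  return shares;
}

// ---- k-NN distances and DBSCAN -------------------------------------------

static inline double dist2_pbc(const NumericMatrix &p, int i, int j,
                               const double *L) {
  double s = 0.0;
  for (int d = 0; d < 3; ++d) {
    double dd = p(i, d) - p(j, d);
    if (L) dd = min_image(dd, L[d]);
    s += dd * dd;
  }
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_knn_dist(NumericMatrix points, int k,
                           Nullable<NumericVector> box = R_NilValue) {
  int n = points.nrow();
  if (k < 1 || k > n - 1) stop("need at least k+1 points");
  const double *L = nullptr;
  NumericVector boxv;
  if (box.isNotNull()) { boxv = box.get(); L = boxv.begin(); }
  NumericVector out(n);
  std::vector<double> d2(n);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j)
      if (j != i) d2[m++] = dist2_pbc(points, i, j, L);
    std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.begin() + m);
    out[i] = std::sqrt(d2[k - 1]);
  }
  return out;
}

// Standard DBSCAN. A point is a core point if its eps-neighborhood,
// including the point itself, holds at least min_pts points. Cluster ids
// are 1-based in order of discovery; noise is 0. Deterministic given point
// order.
// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericMatrix points, double eps, int min_pts,
                         Nullable<NumericVector> box = R_NilValue) {
  int n = points.nrow();
  if (eps <= 0) stop("eps must be positive");
  const double *L = nullptr;
  NumericVector boxv;
  if (box.isNotNull()) { boxv = box.get(); L = boxv.begin(); }
  double eps2 = eps * eps;

  // neighbor lists (self excluded here; core rule adds 1)
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (dist2_pbc(points, i, j, L) <= eps2) {
        nb[i].push_back(j);
        nb[j].push_back(i);
      }

  IntegerVector labels(n, 0);
  std::vector<char> visited(n, 0);
  int cid = 0;
  std::vector<int> queue;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = 1;
    if ((int)nb[i].size() + 1 < min_pts) continue; // noise unless claimed
    ++cid;
    labels[i] = cid;
    queue.assign(nb[i].begin(), nb[i].end());
    for (size_t q = 0; q < queue.size(); ++q) {
      int j = queue[q];
      if (labels[j] == 0) labels[j] = cid; // border or core, first cluster
      if (visited[j]) continue;
      visited[j] = 1;
      if ((int)nb[j].size() + 1 >= min_pts)
        for (int m : nb[j]) queue.push_back(m);
    }
  }
  return labels;
}
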
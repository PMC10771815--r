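// Coarse-grained force field and Langevin integrator.
//
// Internal unit convention: the caller supplies positions, sigma and cutoffs
// in one length unit, energies (epsilon, kT, bond_k) in one energy unit, and
// masses, dt, gamma in units consistent with F = m a.  The R wrappers perform
// the real-unit (Angstrom / kcal/mol / amu / fs) conversions.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>

using namespace Rcpp;

static inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

// ---------------------------------------------------------------------------
// Pair enumeration
// ---------------------------------------------------------------------------

// Brute-force O(n^2) enumeration of pairs with r < cutoff (minimum image).
static void pairs_brute(const std::vector<double>& x, const NumericVector& box,
                        double cutoff, std::vector<int>& pi, std::vector<int>& pj) {
  const int n = (int)x.size() / 3;
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(x[3 * i]     - x[3 * j],     box[0]);
      double dy = min_image(x[3 * i + 1] - x[3 * j + 1], box[1]);
      double dz = min_image(x[3 * i + 2] - x[3 * j + 2], box[2]);
      if (dx * dx + dy * dy + dz * dz < c2) { pi.push_back(i); pj.push_back(j); }
    }
  }
}

// Linked-cell enumeration; requires >= 3 cells per edge, else falls back.
static void pairs_cell(const std::vector<double>& x, const NumericVector& box,
                       double cutoff, std::vector<int>& pi, std::vector<int>& pj) {
  const int n = (int)x.size() / 3;
  int nc[3];
  for (int k = 0; k < 3; ++k) nc[k] = (int)std::floor(box[k] / cutoff);
  if (nc[0] < 3 || nc[1] < 3 || nc[2] < 3) { pairs_brute(x, box, cutoff, pi, pj); return; }
  const int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncell, -1), next(n, -1), cell_of(n);
  for (int i = 0; i < n; ++i) {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      double w = x[3 * i + k] - box[k] * std::floor(x[3 * i + k] / box[k]);
      int ci = (int)(w / box[k] * nc[k]);
      if (ci >= nc[k]) ci = nc[k] - 1;
      if (ci < 0) ci = 0;
      c[k] = ci;
    }
    int idx = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
    cell_of[i] = idx;
    next[i] = head[idx];
    head[idx] = i;
  }
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    int ci = cell_of[i];
    int cx = ci % nc[0], cy = (ci / nc[0]) % nc[1], cz = ci / (nc[0] * nc[1]);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int ex = (cx + dx + nc[0]) % nc[0];
          int ey = (cy + dy + nc[1]) % nc[1];
          int ez = (cz + dz + nc[2]) % nc[2];
          int cj = (ez * nc[1] + ey) * nc[0] + ex;
          for (int j = head[cj]; j != -1; j = next[j]) {
            if (j <= i) continue;
            double ddx = min_image(x[3 * i]     - x[3 * j],     box[0]);
            double ddy = min_image(x[3 * i + 1] - x[3 * j + 1], box[1]);
            double ddz = min_image(x[3 * i + 2] - x[3 * j + 2], box[2]);
            if (ddx * ddx + ddy * ddy + ddz * ddz < c2) { pi.push_back(i); pj.push_back(j); }
          }
        }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_pair_list(NumericMatrix pos, NumericVector box, double cutoff,
                            std::string method) {
  const int n = pos.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  std::vector<int> pi, pj;
  if (method == "brute") pairs_brute(x, box, cutoff, pi, pj);
  else pairs_cell(x, box, cutoff, pi, pj);
  IntegerMatrix out((int)pi.size(), 2);
  for (int r = 0; r < (int)pi.size(); ++r) { out(r, 0) = pi[r] + 1; out(r, 1) = pj[r] + 1; }
  return out;
}

// ---------------------------------------------------------------------------
// Energy / force kernel
// ---------------------------------------------------------------------------

struct FFParams {
  NumericVector sigma, lambda, charge;
  double epsilon, bond_k, bond_r0, debye_len, coul_pref;
  double pair_cutoff, coul_cutoff;
  bool any_charge;
};

// Ashbaugh-Hatch pair energy/derivative (cutoff-shifted).
static inline void ah_pair(double r, double sig, double lam, double eps,
                           double rc, double& u, double& dudr) {
  double s2c = sig * sig / (rc * rc);
  double s6c = s2c * s2c * s2c;
  double uljc = 4.0 * eps * (s6c * s6c - s6c);
  double s2 = sig * sig / (r * r);
  double s6 = s2 * s2 * s2;
  double ulj = 4.0 * eps * (s6 * s6 - s6);
  double dulj = 4.0 * eps * (-12.0 * s6 * s6 + 6.0 * s6) / r;
  double rmin = 1.122462048309373 * sig;  // 2^(1/6) sigma
  if (r <= rmin) {
    u = ulj + (1.0 - lam) * eps - lam * uljc;
    dudr = dulj;
  } else {
    u = lam * (ulj - uljc);
    dudr = lam * dulj;
  }
}

// chain: 1-based chain id per bead; consecutive beads of the same chain are bonded.
static double forces_core(const std::vector<double>& x, const NumericVector& box,
                          const IntegerVector& chain, const FFParams& p,
                          std::vector<double>* f, int neighbor,
                          double* e_pair, double* e_bond, double* e_coul) {
  const int n = (int)x.size() / 3;
  if (f) f->assign(3 * n, 0.0);
  double rmax = p.pair_cutoff;
  if (p.any_charge && p.coul_cutoff > rmax) rmax = p.coul_cutoff;
  std::vector<int> pi, pj;
  bool use_cell = (neighbor == 2) ||
    (neighbor == 0 && n > 256 &&
     box[0] >= 3 * rmax && box[1] >= 3 * rmax && box[2] >= 3 * rmax);
  if (use_cell) pairs_cell(x, box, rmax, pi, pj);
  else pairs_brute(x, box, rmax, pi, pj);

  double ep = 0.0, eb = 0.0, ec = 0.0;
  const double floor_r = 1e-6;
  for (size_t q = 0; q < pi.size(); ++q) {
    int i = pi[q], j = pj[q];
    if (chain[i] == chain[j] && std::abs(i - j) == 1) continue;  // bonded: excluded
    double dx = min_image(x[3 * i]     - x[3 * j],     box[0]);
    double dy = min_image(x[3 * i + 1] - x[3 * j + 1], box[1]);
    double dz = min_image(x[3 * i + 2] - x[3 * j + 2], box[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < floor_r)
      stop("overlapping beads %d and %d (r = %g)", i + 1, j + 1, r);
    double dudr_tot = 0.0;
    if (p.epsilon != 0.0 && r < p.pair_cutoff) {
      double sig = 0.5 * (p.sigma[i] + p.sigma[j]);
      double lam = 0.5 * (p.lambda[i] + p.lambda[j]);
      double u, dudr;
      ah_pair(r, sig, lam, p.epsilon, p.pair_cutoff, u, dudr);
      ep += u;
      dudr_tot += dudr;
    }
    if (p.any_charge && r < p.coul_cutoff) {
      double qq = p.charge[i] * p.charge[j];
      if (qq != 0.0) {
        double uc = p.coul_pref * qq / r * std::exp(-r / p.debye_len);
        double ushift = p.coul_pref * qq / p.coul_cutoff *
                        std::exp(-p.coul_cutoff / p.debye_len);
        ec += uc - ushift;
        dudr_tot += -uc * (1.0 / r + 1.0 / p.debye_len);
      }
    }
    if (f && dudr_tot != 0.0) {
      double fac = -dudr_tot / r;
      (*f)[3 * i]     += fac * dx; (*f)[3 * j]     -= fac * dx;
      (*f)[3 * i + 1] += fac * dy; (*f)[3 * j + 1] -= fac * dy;
      (*f)[3 * i + 2] += fac * dz; (*f)[3 * j + 2] -= fac * dz;
    }
  }
  // harmonic bonds U = k (r - r0)^2
  if (p.bond_k != 0.0) {
    for (int i = 0; i < n - 1; ++i) {
      if (chain[i] != chain[i + 1]) continue;
      double dx = min_image(x[3 * i]     - x[3 * (i + 1)],     box[0]);
      double dy = min_image(x[3 * i + 1] - x[3 * (i + 1) + 1], box[1]);
      double dz = min_image(x[3 * i + 2] - x[3 * (i + 1) + 2], box[2]);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < floor_r)
        stop("overlapping bonded beads %d and %d (r = %g)", i + 1, i + 2, r);
      eb += p.bond_k * (r - p.bond_r0) * (r - p.bond_r0);
      if (f) {
        double dudr = 2.0 * p.bond_k * (r - p.bond_r0);
        double fac = -dudr / r;
        (*f)[3 * i]           += fac * dx; (*f)[3 * (i + 1)]     -= fac * dx;
        (*f)[3 * i + 1]       += fac * dy; (*f)[3 * (i + 1) + 1] -= fac * dy;
        (*f)[3 * i + 2]       += fac * dz; (*f)[3 * (i + 1) + 2] -= fac * dz;
      }
    }
  }
  if (e_pair) *e_pair = ep;
  if (e_bond) *e_bond = eb;
  if (e_coul) *e_coul = ec;
  return ep + eb + ec;
}

static FFParams unpack(NumericVector sigma, NumericVector lambda, NumericVector charge,
                       double epsilon, double bond_k, double bond_r0,
                       double debye_len, double coul_pref,
                       double pair_cutoff, double coul_cutoff) {
  FFParams p{sigma, lambda, charge, epsilon, bond_k, bond_r0,
             debye_len, coul_pref, pair_cutoff, coul_cutoff, false};
  for (int i = 0; i < charge.size(); ++i)
    if (charge[i] != 0.0) { p.any_charge = true; break; }
  return p;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericVector box, IntegerVector chain,
                NumericVector sigma, NumericVector lambda, NumericVector charge,
                double epsilon, double bond_k, double bond_r0,
                double debye_len, double coul_pref,
                double pair_cutoff, double coul_cutoff,
                bool want_forces, int neighbor) {
  const int n = pos.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  FFParams p = unpack(sigma, lambda, charge, epsilon, bond_k, bond_r0,
                      debye_len, coul_pref, pair_cutoff, coul_cutoff);
  std::vector<double> f;
  std::vector<double>* fp = nullptr;
  if (want_forces) { f.assign(3 * n, 0.0); fp = &f; }
  double ep, eb, ec;
  double e = forces_core(x, box, chain, p, fp, neighbor, &ep, &eb, &ec);
  List out = List::create(_["energy"] = e, _["e_pair"] = ep,
                          _["e_bond"] = eb, _["e_coul"] = ec);
  if (want_forces) {
    NumericMatrix fm(n, 3);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) fm(i, k) = f[3 * i + k];
    out["forces"] = fm;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Langevin dynamics (BAOAB splitting)
// ---------------------------------------------------------------------------

// Deterministic Gaussian generator (Box-Muller over mt19937_64) so that seeded
// runs are bit-reproducible on a given platform regardless of libstdc++.
struct Gauss {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit Gauss(uint64_t seed) : eng(seed) {}
  double unif() { return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double operator()() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(6.283185307179586 * u2);
    has_spare = true;
    return r * std::cos(6.283185307179586 * u2);
  }
};

// [[Rcpp::export]]
List cpp_langevin(NumericMatrix pos0, NumericVector box, IntegerVector chain,
                  NumericVector sigma, NumericVector lambda, NumericVector charge,
                  NumericVector mass,
                  double epsilon, double bond_k, double bond_r0,
                  double debye_len, double coul_pref,
                  double pair_cutoff, double coul_cutoff,
                  double dt, double gamma, double kT,
                  int n_steps, int save_every, int seed,
                  bool draw_velocities, Nullable<NumericMatrix> vel0) {
  const int n = pos0.nrow();
  std::vector<double> x(3 * n), v(3 * n, 0.0), f(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos0(i, k);
  FFParams p = unpack(sigma, lambda, charge, epsilon, bond_k, bond_r0,
                      debye_len, coul_pref, pair_cutoff, coul_cutoff);
  Gauss g((uint64_t)seed * 2654435761u + 1u);
  if (draw_velocities) {
    for (int i = 0; i < n; ++i) {
      double sd = std::sqrt(kT / mass[i]);
      for (int k = 0; k < 3; ++k) v[3 * i + k] = sd * g();
    }
  } else if (vel0.isNotNull()) {
    NumericMatrix vv(vel0);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v[3 * i + k] = vv(i, k);
  }
  const double c1 = std::exp(-gamma * dt);
  const double maxdisp = 0.5 * std::min(box[0], std::min(box[1], box[2]));
  double epot = forces_core(x, box, chain, p, &f, 0, nullptr, nullptr, nullptr);

  int n_save = n_steps / save_every;
  List frames(n_save);
  NumericVector save_step(n_save), save_epot(n_save), save_kT(n_save);
  int isave = 0;

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double im = 0.5 * dt / mass[i];
      for (int k = 0; k < 3; ++k) v[3 * i + k] += im * f[3 * i + k];
    }
    std::vector<double> xold(x);
    for (int q = 0; q < 3 * n; ++q) x[q] += 0.5 * dt * v[q];
    for (int i = 0; i < n; ++i) {
      double c2 = std::sqrt(kT / mass[i] * (1.0 - c1 * c1));
      for (int k = 0; k < 3; ++k)
        v[3 * i + k] = c1 * v[3 * i + k] + c2 * g();
    }
    for (int q = 0; q < 3 * n; ++q) x[q] += 0.5 * dt * v[q];
    for (int q = 0; q < 3 * n; ++q)
      if (std::abs(x[q] - xold[q]) > maxdisp)
        stop("integration diverged at step %d (bead %d moved %g in one step); "
             "reduce dt or check the starting configuration",
             step, q / 3 + 1, std::abs(x[q] - xold[q]));
    epot = forces_core(x, box, chain, p, &f, 0, nullptr, nullptr, nullptr);
    for (int i = 0; i < n; ++i) {
      double im = 0.5 * dt / mass[i];
      for (int k = 0; k < 3; ++k) v[3 * i + k] += im * f[3 * i + k];
    }
    if (step % save_every == 0 && isave < n_save) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) {
          double w = x[3 * i + k];
          fr(i, k) = w - box[k] * std::floor(w / box[k]);  // wrapped copy
        }
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) ke += mass[i] * v[3 * i + k] * v[3 * i + k];
      save_step[isave] = step;
      save_epot[isave] = epot;
      save_kT[isave] = ke / (3.0 * n);  // instantaneous kinetic kT
      frames[isave] = fr;
      ++isave;
    }
  }
  NumericMatrix xfin(n, 3), vfin(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) { xfin(i, k) = x[3 * i + k]; vfin(i, k) = v[3 * i + k]; }
  return List::create(_["frames"] = frames, _["step"] = save_step,
                      _["e_pot"] = save_epot, _["kT_kin"] = save_kT,
                      _["x_final"] = xfin, _["v_final"] = vfin);
}
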
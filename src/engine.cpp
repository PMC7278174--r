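// Coarse-grained force field and BAOAB Langevin integrator.
// Units across the package: A, ps, amu, kcal/mol, elementary charges.
#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 1 kcal/mol = 418.4 amu A^2 ps^-2
static const double AKMA = 418.4;
static const double KBOLTZ = 0.0019872041; // kcal mol^-1 K^-1

struct FFParams {
  int n;
  std::vector<double> mass, charge, sigma, eps;
  std::vector<int> bi, bj;           // 0-based bond indices
  std::vector<double> bk, br0;       // V = 1/2 k (r - r0)^2
  std::unordered_set<long long> excl;
  double box;                        // <= 0 means no box
  double cutoff, cutoff2;
  double coulk;                      // 332.0637 / dielectric
  std::vector<int> ridx;             // 0-based restrained bead indices
  std::vector<double> rk;
  std::vector<double> rref;          // 3 * n_restraint, row-major xyz
  std::vector<char> frozen;
  bool skip_frozen_pairs;
  double floor2;
  std::vector<int> pi, pj;           // precomputed nonbonded pair list
};

static inline double mimg(double d, double box) {
  if (box > 0) d -= box * std::nearbyint(d / box);
  return d;
}

struct EnergyTerms { double bond, lj, coul, restraint; };

static EnergyTerms eval_forces(const FFParams &ff, const double *x, double *f,
                               double t_now) {
  const int n = ff.n;
  std::fill(f, f + 3 * n, 0.0);
  EnergyTerms e = {0.0, 0.0, 0.0, 0.0};

  (void)n;
  // nonbonded, over the precomputed pair list (bonded 1-2 pairs excluded;
  // frozen-frozen pairs excluded when built for the integrator)
  for (size_t p = 0; p < ff.pi.size(); ++p) {
      int i = ff.pi[p], j = ff.pj[p];
      double dx = mimg(x[3 * i]     - x[3 * j],     ff.box);
      double dy = mimg(x[3 * i + 1] - x[3 * j + 1], ff.box);
      double dz = mimg(x[3 * i + 2] - x[3 * j + 2], ff.box);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < ff.floor2)
        stop("beads %d and %d overlap (r = %.4f A) at t = %.4f ps",
             i + 1, j + 1, std::sqrt(r2), t_now);
      if (r2 >= ff.cutoff2) continue;
      double g = 0.0; // (dV/dr)/r ; force on i is -g * (xi - xj)
      double epsij = std::sqrt(ff.eps[i] * ff.eps[j]);
      if (epsij > 0) {
        double sij = 0.5 * (ff.sigma[i] + ff.sigma[j]);
        double s2 = sij * sij / r2;
        double s6 = s2 * s2 * s2;
        double s12 = s6 * s6;
        e.lj += 4.0 * epsij * (s12 - s6);
        g += 24.0 * epsij * (s6 - 2.0 * s12) / r2;
      }
      double qq = ff.coulk * ff.charge[i] * ff.charge[j];
      if (qq != 0.0) {
        double r = std::sqrt(r2);
        e.coul += qq / r;
        g += -qq / (r2 * r);
      }
      if (g != 0.0) {
        f[3 * i]     -= g * dx; f[3 * j]     += g * dx;
        f[3 * i + 1] -= g * dy; f[3 * j + 1] += g * dy;
        f[3 * i + 2] -= g * dz; f[3 * j + 2] += g * dz;
      }
  }

  for (size_t b = 0; b < ff.bi.size(); ++b) {
    int i = ff.bi[b], j = ff.bj[b];
    double dx = mimg(x[3 * i]     - x[3 * j],     ff.box);
    double dy = mimg(x[3 * i + 1] - x[3 * j + 1], ff.box);
    double dz = mimg(x[3 * i + 2] - x[3 * j + 2], ff.box);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-10)
      stop("bonded beads %d and %d are coincident at t = %.4f ps",
           i + 1, j + 1, t_now);
    double dr = r - ff.br0[b];
    e.bond += 0.5 * ff.bk[b] * dr * dr;
    double g = ff.bk[b] * dr / r;
    f[3 * i]     -= g * dx; f[3 * j]     += g * dx;
    f[3 * i + 1] -= g * dy; f[3 * j + 1] += g * dy;
    f[3 * i + 2] -= g * dz; f[3 * j + 2] += g * dz;
  }

  for (size_t m = 0; m < ff.ridx.size(); ++m) {
    int i = ff.ridx[m];
    double dx = x[3 * i]     - ff.rref[3 * m];
    double dy = x[3 * i + 1] - ff.rref[3 * m + 1];
    double dz = x[3 * i + 2] - ff.rref[3 * m + 2];
    e.restraint += 0.5 * ff.rk[m] * (dx * dx + dy * dy + dz * dz);
    f[3 * i]     -= ff.rk[m] * dx;
    f[3 * i + 1] -= ff.rk[m] * dy;
    f[3 * i + 2] -= ff.rk[m] * dz;
  }

  return e;
}

static FFParams build_ff(NumericVector mass, NumericVector charge,
                         NumericVector sigma, NumericVector eps,
                         IntegerVector bond_i, IntegerVector bond_j,
                         NumericVector bond_k, NumericVector bond_r0,
                         double box, double cutoff, double coul_k,
                         IntegerVector restr_idx, NumericVector restr_k,
                         NumericMatrix restr_ref, LogicalVector frozen,
                         bool skip_frozen_pairs, double floor_dist) {
  FFParams ff;
  ff.n = mass.size();
  ff.mass.assign(mass.begin(), mass.end());
  ff.charge.assign(charge.begin(), charge.end());
  ff.sigma.assign(sigma.begin(), sigma.end());
  ff.eps.assign(eps.begin(), eps.end());
  for (int b = 0; b < bond_i.size(); ++b) {
    int i = bond_i[b] - 1, j = bond_j[b] - 1;
    if (i > j) std::swap(i, j);
    ff.bi.push_back(i); ff.bj.push_back(j);
    ff.bk.push_back(bond_k[b]); ff.br0.push_back(bond_r0[b]);
    ff.excl.insert((long long)i * ff.n + j); // 1-2 pairs excluded from nonbonded
  }
  ff.box = box;
  ff.cutoff = cutoff;
  ff.cutoff2 = cutoff * cutoff;
  ff.coulk = coul_k;
  for (int m = 0; m < restr_idx.size(); ++m) {
    ff.ridx.push_back(restr_idx[m] - 1);
    ff.rk.push_back(restr_k[m]);
    ff.rref.push_back(restr_ref(m, 0));
    ff.rref.push_back(restr_ref(m, 1));
    ff.rref.push_back(restr_ref(m, 2));
  }
  ff.frozen.assign(ff.n, 0);
  for (int i = 0; i < frozen.size(); ++i) ff.frozen[i] = frozen[i] ? 1 : 0;
  ff.skip_frozen_pairs = skip_frozen_pairs;
  ff.floor2 = floor_dist * floor_dist;
  for (int i = 0; i < ff.n - 1; ++i) {
    for (int j = i + 1; j < ff.n; ++j) {
      if (ff.skip_frozen_pairs && ff.frozen[i] && ff.frozen[j]) continue;
      if (!ff.excl.empty() && ff.excl.count((long long)i * ff.n + j))
        continue;
      ff.pi.push_back(i);
      ff.pj.push_back(j);
    }
  }
  return ff;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix coords, NumericVector mass, NumericVector charge,
                NumericVector sigma, NumericVector eps,
                IntegerVector bond_i, IntegerVector bond_j,
                NumericVector bond_k, NumericVector bond_r0,
                double box, double cutoff, double coul_k,
                IntegerVector restr_idx, NumericVector restr_k,
                NumericMatrix restr_ref, LogicalVector frozen,
                bool skip_frozen_pairs, double floor_dist) {
  FFParams ff = build_ff(mass, charge, sigma, eps, bond_i, bond_j, bond_k,
                         bond_r0, box, cutoff, coul_k, restr_idx, restr_k,
                         restr_ref, frozen, skip_frozen_pairs, floor_dist);
  int n = ff.n;
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  EnergyTerms e = eval_forces(ff, x.data(), f.data(), 0.0);
  NumericMatrix fo(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) fo(i, d) = f[3 * i + d];
  return List::create(_["forces"] = fo, _["e_bond"] = e.bond,
                      _["e_lj"] = e.lj, _["e_coul"] = e.coul,
                      _["e_restraint"] = e.restraint);
}

// BAOAB splitting of Langevin dynamics; deterministic given R's RNG state.
// [[Rcpp::export]]
List cpp_segment(NumericMatrix coords, NumericMatrix vel,
                 NumericVector mass, NumericVector charge,
                 NumericVector sigma, NumericVector eps,
                 IntegerVector bond_i, IntegerVector bond_j,
                 NumericVector bond_k, NumericVector bond_r0,
                 double box, double cutoff, double coul_k,
                 IntegerVector restr_idx, NumericVector restr_k,
                 NumericMatrix restr_ref, LogicalVector frozen,
                 double floor_dist, double dt, int n_steps, int save_every,
                 double temperature, double friction, double t0) {
  FFParams ff = build_ff(mass, charge, sigma, eps, bond_i, bond_j, bond_k,
                         bond_r0, box, cutoff, coul_k, restr_idx, restr_k,
                         restr_ref, frozen, true, floor_dist);
  const int n = ff.n;
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  std::vector<int> mobile;
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = coords(i, d);
      v[3 * i + d] = ff.frozen[i] ? 0.0 : vel(i, d);
    }
    if (!ff.frozen[i]) mobile.push_back(i);
  }
  const int nmob = (int)mobile.size();
  if (nmob == 0) stop("no mobile beads to integrate");

  double c1 = (friction > 0) ? std::exp(-friction * dt) : 1.0;
  std::vector<double> sig(n, 0.0), bfac(n, 0.0);
  for (int i = 0; i < n; ++i) {
    if (ff.frozen[i]) continue;
    bfac[i] = 0.5 * dt * AKMA / ff.mass[i];
    if (friction > 0 && temperature > 0)
      sig[i] = std::sqrt(KBOLTZ * temperature * AKMA / ff.mass[i] *
                         (1.0 - c1 * c1));
  }

  const int nsave = n_steps / save_every;
  NumericVector frames(Dimension(nsave, n, 3));
  NumericMatrix energies(nsave, 6); // t, bond, lj, coul, restraint, T_inst

  EnergyTerms e = eval_forces(ff, x.data(), f.data(), t0);
  for (int s = 0; s < n_steps; ++s) {
    double t_now = t0 + (s + 1) * dt;
    for (int k = 0; k < nmob; ++k) {            // B
      int i = mobile[k];
      for (int d = 0; d < 3; ++d) v[3 * i + d] += bfac[i] * f[3 * i + d];
    }
    for (int k = 0; k < nmob; ++k) {            // A
      int i = mobile[k];
      for (int d = 0; d < 3; ++d) x[3 * i + d] += 0.5 * dt * v[3 * i + d];
    }
    for (int k = 0; k < nmob; ++k) {            // O
      int i = mobile[k];
      for (int d = 0; d < 3; ++d)
        v[3 * i + d] = c1 * v[3 * i + d] + sig[i] * norm_rand();
    }
    for (int k = 0; k < nmob; ++k) {            // A
      int i = mobile[k];
      for (int d = 0; d < 3; ++d) x[3 * i + d] += 0.5 * dt * v[3 * i + d];
    }
    e = eval_forces(ff, x.data(), f.data(), t_now);
    for (int k = 0; k < nmob; ++k) {            // B
      int i = mobile[k];
      for (int d = 0; d < 3; ++d) v[3 * i + d] += bfac[i] * f[3 * i + d];
    }
    if ((s + 1) % save_every == 0) {
      int fi = (s + 1) / save_every - 1;
      double ke = 0.0;
      bool ok = true;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) {
          double xi = x[3 * i + d];
          frames[fi + (long long)nsave * (i + (long long)n * d)] = xi;
          if (!std::isfinite(xi)) ok = false;
        }
      for (int k = 0; k < nmob; ++k) {
        int i = mobile[k];
        for (int d = 0; d < 3; ++d)
          ke += ff.mass[i] * v[3 * i + d] * v[3 * i + d];
      }
      ke *= 0.5 / AKMA;
      double etot = e.bond + e.lj + e.coul + e.restraint;
      if (!ok || !std::isfinite(etot))
        stop("non-finite coordinates or energy at t = %.4f ps", t_now);
      energies(fi, 0) = t_now;
      energies(fi, 1) = e.bond;
      energies(fi, 2) = e.lj;
      energies(fi, 3) = e.coul;
      energies(fi, 4) = e.restraint;
      energies(fi, 5) = 2.0 * ke / (3.0 * nmob * KBOLTZ);
    }
  }

  NumericMatrix xo(n, 3), vo(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      xo(i, d) = x[3 * i + d];
      vo(i, d) = v[3 * i + d];
    }
  return List::create(_["frames"] = frames, _["energies"] = energies,
                      _["coords"] = xo, _["velocities"] = vo);
}
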
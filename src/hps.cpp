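#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Deterministic RNG: xoshiro-free minimal splitmix64 + explicit Box-Muller,
// so trajectories are bit-identical for a given seed independent of the
// standard library's distribution implementations.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ^ 0x9E3779B97F4A7C15ULL) {}
  uint64_t next_u64() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() {  // (0, 1)
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

static const double KB = 0.00831446261815324;  // kJ/mol/K
static const double CBRT2 = 1.2599210498948732;  // 2^(1/3)

struct PairParams {
  std::vector<double> lambda, sigma, charge;
  double eps, cutoff2, dh_cutoff2, bjerrum, kappa_inv;  // kappa_inv = 1/debye
};

// Ashbaugh-Hatch modified WCA + screened Coulomb for one pair.
// Returns energy; sets fr = -dU/dr / r (so force on i is fr * (xi - xj)).
static inline double pair_eu(double r2, double li, double lj, double si,
                             double sj, double qi, double qj,
                             const PairParams& pp, double& fr) {
  double e = 0.0;
  fr = 0.0;
  if (r2 < pp.cutoff2) {
    double lam = 0.5 * (li + lj);
    double sij = 0.5 * (si + sj);
    double s2 = sij * sij / r2;
    double s6 = s2 * s2 * s2;
    double s12 = s6 * s6;
    double phi = 4.0 * pp.eps * (s12 - s6);
    double dphi_r = 4.0 * pp.eps * (-12.0 * s12 + 6.0 * s6) / r2;  // dPhi/dr / r
    double rmin2 = sij * sij * CBRT2;
    if (r2 <= rmin2) {
      e += phi + (1.0 - lam) * pp.eps;
      fr += -dphi_r;
    } else {
      e += lam * phi;
      fr += -lam * dphi_r;
    }
  }
  if (qi != 0.0 && qj != 0.0 && r2 < pp.dh_cutoff2) {
    double r = std::sqrt(r2);
    double pref = pp.bjerrum * qi * qj;
    double ed = pref * std::exp(-r * pp.kappa_inv) / r;
    e += ed;
    // dU/dr = -ed*(1/r + kappa_inv); force fr = -dU/dr / r
    fr += ed * (1.0 / r + pp.kappa_inv) / r;
  }
  return e;
}

struct Excl {
  // dense n x n exclusion bitmap (bead counts here are small)
  std::vector<char> map;
  int n;
  void build(const IntegerMatrix& bonds, int n_) {
    n = n_;
    map.assign((size_t)n * n, 0);
    for (int b = 0; b < bonds.nrow(); b++) {
      int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
      map[(size_t)i * n + j] = 1;
      map[(size_t)j * n + i] = 1;
    }
  }
  bool has(int i, int j) const { return map[(size_t)i * n + j] != 0; }
};

// total nonbonded + bonded potential and forces for one configuration
static double total_forces(const std::vector<double>& x, int n,
                           const PairParams& pp, const Excl& ex,
                           const IntegerMatrix& bonds,
                           const NumericVector& bond_r0,
                           const NumericVector& bond_k,
                           const IntegerMatrix& angles,
                           const NumericVector& angle_k,
                           const NumericVector& angle_t0,
                           std::vector<double>& f) {
  std::fill(f.begin(), f.end(), 0.0);
  double u = 0.0;
  for (int i = 0; i < n - 1; i++) {
    double xi = x[3 * i], yi = x[3 * i + 1], zi = x[3 * i + 2];
    for (int j = i + 1; j < n; j++) {
      if (ex.has(i, j)) continue;
      double dx = xi - x[3 * j], dy = yi - x[3 * j + 1], dz = zi - x[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= pp.dh_cutoff2 && r2 >= pp.cutoff2) continue;
      double fr;
      u += pair_eu(r2, pp.lambda[i], pp.lambda[j], pp.sigma[i], pp.sigma[j],
                   pp.charge[i], pp.charge[j], pp, fr);
      f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
      f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
    }
  }
  // harmonic bonds U = (k/2)(r - r0)^2
  for (int b = 0; b < bonds.nrow(); b++) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - bond_r0[b];
    u += 0.5 * bond_k[b] * dr * dr;
    double fr = -bond_k[b] * dr / r;
    f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
    f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
  }
  // harmonic angles U = (k/2)(theta - theta0)^2, centered on bead j
  for (int a = 0; a < angles.nrow(); a++) {
    int i = angles(a, 0) - 1, j = angles(a, 1) - 1, k = angles(a, 2) - 1;
    double v1x = x[3 * i] - x[3 * j], v1y = x[3 * i + 1] - x[3 * j + 1],
           v1z = x[3 * i + 2] - x[3 * j + 2];
    double v2x = x[3 * k] - x[3 * j], v2y = x[3 * k + 1] - x[3 * j + 1],
           v2z = x[3 * k + 2] - x[3 * j + 2];
    double n1 = std::sqrt(v1x * v1x + v1y * v1y + v1z * v1z);
    double n2 = std::sqrt(v2x * v2x + v2y * v2y + v2z * v2z);
    double c = (v1x * v2x + v1y * v2y + v1z * v2z) / (n1 * n2);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    double dth = th - angle_t0[a];
    u += 0.5 * angle_k[a] * dth * dth;
    double s = std::sqrt(std::max(1.0 - c * c, 1e-12));
    double coef = -angle_k[a] * dth / s;  // dU/dcos(theta) chain
    // dcos/dxi etc.
    double f1x = coef * (v2x / (n1 * n2) - c * v1x / (n1 * n1));
    double f1y = coef * (v2y / (n1 * n2) - c * v1y / (n1 * n1));
    double f1z = coef * (v2z / (n1 * n2) - c * v1z / (n1 * n1));
    double f2x = coef * (v1x / (n1 * n2) - c * v2x / (n2 * n2));
    double f2y = coef * (v1y / (n1 * n2) - c * v2y / (n2 * n2));
    double f2z = coef * (v1z / (n1 * n2) - c * v2z / (n2 * n2));
    f[3 * i] -= f1x; f[3 * i + 1] -= f1y; f[3 * i + 2] -= f1z;
    f[3 * k] -= f2x; f[3 * k + 1] -= f2y; f[3 * k + 2] -= f2z;
    f[3 * j] += f1x + f2x; f[3 * j + 1] += f1y + f2y; f[3 * j + 2] += f1z + f2z;
  }
  return u;
}

static PairParams make_pp(const NumericVector& lambda,
                          const NumericVector& sigma,
                          const NumericVector& charge, double eps,
                          double cutoff, double dh_cutoff, double bjerrum,
                          double debye_length) {
  PairParams pp;
  pp.lambda.assign(lambda.begin(), lambda.end());
  pp.sigma.assign(sigma.begin(), sigma.end());
  pp.charge.assign(charge.begin(), charge.end());
  pp.eps = eps;
  pp.cutoff2 = cutoff * cutoff;
  pp.dh_cutoff2 = dh_cutoff * dh_cutoff;
  pp.bjerrum = bjerrum;
  pp.kappa_inv = 1.0 / debye_length;
  return pp;
}

// [[Rcpp::export]]
List hps_run_langevin(NumericMatrix x0, NumericVector lambda,
                      NumericVector sigma, NumericVector charge,
                      NumericVector mass, IntegerMatrix bonds,
                      NumericVector bond_r0, NumericVector bond_k,
                      IntegerMatrix angles, NumericVector angle_k,
                      NumericVector angle_t0, double eps, double cutoff,
                      double dh_cutoff, double bjerrum, double debye_length,
                      double temperature, double dt_ps, double friction_ps,
                      double n_steps, int stride, double seed,
                      double energy_abort, int minimize_steps) {
  int n = x0.nrow();
  PairParams pp = make_pp(lambda, sigma, charge, eps, cutoff, dh_cutoff,
                          bjerrum, debye_length);
  Excl ex; ex.build(bonds, n);
  Rng rng((uint64_t)seed);

  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; i++)
    for (int d = 0; d < 3; d++) x[3 * i + d] = x0(i, d);
  double kT = KB * temperature;
  // Maxwell-Boltzmann initial velocities
  for (int i = 0; i < n; i++) {
    double sv = std::sqrt(kT / mass[i]);
    for (int d = 0; d < 3; d++) v[3 * i + d] = sv * rng.norm();
  }
  // displacement-capped steepest descent to relax overlaps in the
  // starting structure before dynamics
  for (int m = 0; m < minimize_steps; m++) {
    total_forces(x, n, pp, ex, bonds, bond_r0, bond_k, angles, angle_k,
                 angle_t0, f);
    double fmax = 1e-12;
    for (int k = 0; k < 3 * n; k++)
      fmax = std::max(fmax, std::fabs(f[k]));
    double scale = std::min(0.01 / fmax, 1e-4);
    for (int k = 0; k < 3 * n; k++) x[k] += scale * f[k];
  }

  double c1 = std::exp(-friction_ps * dt_ps);
  double c2 = std::sqrt(1.0 - c1 * c1);

  long steps = (long)n_steps;
  int n_frames = (int)(steps / stride);
  NumericVector frames(3.0 * n * n_frames);
  NumericVector pot(n_frames), kin(n_frames);
  double ke_accum = 0.0;
  long ke_count = 0;

  double u = total_forces(x, n, pp, ex, bonds, bond_r0, bond_k, angles,
                          angle_k, angle_t0, f);
  int fi = 0;
  for (long s = 1; s <= steps; s++) {
    // BAOAB
    for (int i = 0; i < n; i++) {
      double im = 0.5 * dt_ps / mass[i];
      for (int d = 0; d < 3; d++) v[3 * i + d] += im * f[3 * i + d];
    }
    for (int k = 0; k < 3 * n; k++) x[k] += 0.5 * dt_ps * v[k];
    for (int i = 0; i < n; i++) {
      double sv = std::sqrt(kT / mass[i]);
      for (int d = 0; d < 3; d++)
        v[3 * i + d] = c1 * v[3 * i + d] + c2 * sv * rng.norm();
    }
    for (int k = 0; k < 3 * n; k++) x[k] += 0.5 * dt_ps * v[k];
    u = total_forces(x, n, pp, ex, bonds, bond_r0, bond_k, angles, angle_k,
                     angle_t0, f);
    for (int i = 0; i < n; i++) {
      double im = 0.5 * dt_ps / mass[i];
      for (int d = 0; d < 3; d++) v[3 * i + d] += im * f[3 * i + d];
    }
    if (!std::isfinite(u) || std::fabs(u) > energy_abort)
      stop("energy divergence at step %ld (U = %g kJ/mol)", s, u);
    double ke = 0.0;
    for (int i = 0; i < n; i++)
      for (int d = 0; d < 3; d++)
        ke += 0.5 * mass[i] * v[3 * i + d] * v[3 * i + d];
    ke_accum += ke;
    ke_count++;
    if (s % stride == 0 && fi < n_frames) {
      for (int k = 0; k < 3 * n; k++) frames[(int64_t)3 * n * fi + k] = x[k];
      pot[fi] = u;
      kin[fi] = ke;
      fi++;
    }
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  frames.attr("dim") = IntegerVector::create(3, n, n_frames);
  return List::create(_["frames"] = frames, _["potential"] = pot,
                      _["kinetic"] = kin,
                      _["mean_kinetic"] = ke_accum / ke_count,
                      _["n_frames"] = n_frames);
}

// Recompute total potential on stored frames (same model as the integrator)
// [[Rcpp::export]]
NumericVector hps_potential_frames(NumericVector frames, NumericVector lambda,
                                   NumericVector sigma, NumericVector charge,
                                   IntegerMatrix bonds, NumericVector bond_r0,
                                   NumericVector bond_k, IntegerMatrix angles,
                                   NumericVector angle_k,
                                   NumericVector angle_t0, double eps,
                                   double cutoff, double dh_cutoff,
                                   double bjerrum, double debye_length) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[1], nf = dim[2];
  PairParams pp = make_pp(lambda, sigma, charge, eps, cutoff, dh_cutoff,
                          bjerrum, debye_length);
  Excl ex; ex.build(bonds, n);
  NumericVector out(nf);
  std::vector<double> x(3 * n), f(3 * n);
  for (int fr = 0; fr < nf; fr++) {
    for (int k = 0; k < 3 * n; k++) x[k] = frames[(int64_t)3 * n * fr + k];
    out[fr] = total_forces(x, n, pp, ex, bonds, bond_r0, bond_k, angles,
                           angle_k, angle_t0, f);
  }
  return out;
}

// Per-frame derivative of the short-range potential wrt the lambda of each
// bead type: u_k = sum over pairs of (delta_{ti,k} + delta_{tj,k})/2 *
// dU_pair/dlambda_ij. For r <= 2^{1/6} sigma_ij, dU/dlambda_ij = -eps;
// beyond, it is the plain LJ value Phi(r) (zero past the cutoff).
// [[Rcpp::export]]
NumericMatrix hps_dudlam_frames(NumericVector frames, IntegerVector type_idx,
                                NumericVector sigma, IntegerMatrix bonds,
                                double eps, double cutoff, int n_types) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[1], nf = dim[2];
  Excl ex; ex.build(bonds, n);
  NumericMatrix out(nf, n_types);
  double cutoff2 = cutoff * cutoff;
  for (int fr = 0; fr < nf; fr++) {
    const double* x = &frames[(int64_t)3 * n * fr];
    for (int i = 0; i < n - 1; i++) {
      for (int j = i + 1; j < n; j++) {
        if (ex.has(i, j)) continue;
        double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
               dz = x[3 * i + 2] - x[3 * j + 2];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= cutoff2) continue;
        double sij = 0.5 * (sigma[i] + sigma[j]);
        double s2 = sij * sij / r2;
        double s6 = s2 * s2 * s2;
        double rmin2 = sij * sij * CBRT2;
        double du = (r2 <= rmin2) ? -eps : 4.0 * eps * (s6 * s6 - s6);
        int ti = type_idx[i], tj = type_idx[j];
        out(fr, ti) += 0.5 * du;
        out(fr, tj) += 0.5 * du;
      }
    }
  }
  return out;
}

// Weighted mean squared inter-site distance matrix over frames
// [[Rcpp::export]]
NumericMatrix ens_mean_sq_dist(NumericVector frames, NumericVector w) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[1], nf = dim[2];
  NumericMatrix out(n, n);
  double wsum = 0.0;
  for (int fr = 0; fr < nf; fr++) wsum += w[fr];
  for (int fr = 0; fr < nf; fr++) {
    const double* x = &frames[(int64_t)3 * n * fr];
    double wf = w[fr] / wsum;
    for (int i = 0; i < n - 1; i++)
      for (int j = i + 1; j < n; j++) {
        double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
               dz = x[3 * i + 2] - x[3 * j + 2];
        double r2 = dx * dx + dy * dy + dz * dz;
        out(i, j) += wf * r2;
      }
  }
  for (int i = 0; i < n; i++)
    for (int j = 0; j < i; j++) out(i, j) = out(j, i);
  return out;
}

// Weighted contact probability between residues: a residue pair is in
// contact in a frame when the minimum distance between their sites is
// below the threshold ("closest-heavy" when several sites map to one
// residue; plain bead distance when the mapping is 1:1).
// [[Rcpp::export]]
NumericMatrix ens_contact_prob(NumericVector frames, IntegerVector site_res,
                               int n_res, double threshold, NumericVector w) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[1], nf = dim[2];
  NumericMatrix out(n_res, n_res);
  double wsum = 0.0;
  for (int fr = 0; fr < nf; fr++) wsum += w[fr];
  double t2 = threshold * threshold;
  std::vector<char> hit((size_t)n_res * n_res);
  for (int fr = 0; fr < nf; fr++) {
    const double* x = &frames[(int64_t)3 * n * fr];
    std::fill(hit.begin(), hit.end(), 0);
    for (int i = 0; i < n - 1; i++) {
      int ri = site_res[i] - 1;
      for (int j = i + 1; j < n; j++) {
        int rj = site_res[j] - 1;
        if (ri == rj) continue;
        double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
               dz = x[3 * i + 2] - x[3 * j + 2];
        if (dx * dx + dy * dy + dz * dz < t2) {
          hit[(size_t)ri * n_res + rj] = 1;
          hit[(size_t)rj * n_res + ri] = 1;
        }
      }
    }
    double wf = w[fr] / wsum;
    for (int a = 0; a < n_res; a++)
      for (int b = 0; b < n_res; b++)
        if (hit[(size_t)a * n_res + b]) out(a, b) += wf;
  }
  return out;
}

// Debye-formula scattering profile I(q) = <sum_ij f_i f_j sinc(q r_ij)>
// [[Rcpp::export]]
NumericVector ens_debye_saxs(NumericVector frames, NumericVector ff,
                             NumericVector q, NumericVector w) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[1], nf = dim[2];
  int nq = q.size();
  NumericVector out(nq);
  double wsum = 0.0;
  for (int fr = 0; fr < nf; fr++) wsum += w[fr];
  for (int fr = 0; fr < nf; fr++) {
    const double* x = &frames[(int64_t)3 * n * fr];
    double wf = w[fr] / wsum;
    for (int iq = 0; iq < nq; iq++) {
      double qq = q[iq];
      double s = 0.0;
      for (int i = 0; i < n; i++) s += ff[i] * ff[i];
      for (int i = 0; i < n - 1; i++)
        for (int j = i + 1; j < n; j++) {
          double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
                 dz = x[3 * i + 2] - x[3 * j + 2];
          double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          double sc = (qq * r < 1e-9) ? 1.0 : std::sin(qq * r) / (qq * r);
          s += 2.0 * ff[i] * ff[j] * sc;
        }
      out[iq] += wf * s;
    }
  }
  return out;
}
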
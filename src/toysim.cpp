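// Desk-scale C-alpha bead force field and BAOAB Langevin integrator.
// Units: nm, ps, kJ/mol, K; masses in g/mol. Uses R's RNG stream so runs
// are reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

static const double KB = 0.008314462618; // kJ/mol/K

struct BeadFF {
  double bond_k, bond_r0;
  double angle_k, angle_theta0;
  double ev_sigma, ev_eps;
  double native_eps;
  IntegerMatrix native;     // 1-based residue index pairs
  NumericVector native_r;   // reference distances, nm
  IntegerMatrix restraints; // 1-based residue index pairs
  double sg_A, sg_alpha, sg_r0, sg_k;
  std::vector<signed char> is_native; // n*n lookup for EV exclusion
  int n;
};

static BeadFF parse_ff(const List& ff, int n) {
  BeadFF f;
  f.bond_k = as<double>(ff["bond_k"]);
  f.bond_r0 = as<double>(ff["bond_r0"]);
  f.angle_k = as<double>(ff["angle_k"]);
  f.angle_theta0 = as<double>(ff["angle_theta0"]);
  f.ev_sigma = as<double>(ff["ev_sigma"]);
  f.ev_eps = as<double>(ff["ev_eps"]);
  f.native_eps = as<double>(ff["native_eps"]);
  f.native = as<IntegerMatrix>(ff["native_pairs"]);
  f.native_r = as<NumericVector>(ff["native_r"]);
  f.restraints = as<IntegerMatrix>(ff["restraint_pairs"]);
  f.sg_A = as<double>(ff["sigmoid_A"]);
  f.sg_alpha = as<double>(ff["sigmoid_alpha"]);
  f.sg_r0 = as<double>(ff["sigmoid_r0"]);
  f.sg_k = as<double>(ff["sigmoid_k"]);
  f.n = n;
  f.is_native.assign((size_t)n * n, 0);
  for (int c = 0; c < f.native.nrow(); ++c) {
    int i = f.native(c, 0) - 1, j = f.native(c, 1) - 1;
    f.is_native[(size_t)i * n + j] = 1;
    f.is_native[(size_t)j * n + i] = 1;
  }
  return f;
}

static inline double pair_dist(const NumericMatrix& X, int i, int j,
                               double* dx) {
  dx[0] = X(i, 0) - X(j, 0);
  dx[1] = X(i, 1) - X(j, 1);
  dx[2] = X(i, 2) - X(j, 2);
  return std::sqrt(dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2]);
}

// add radial pair force of magnitude -dVdr along (i - j) direction
static inline void add_pair_force(NumericMatrix& F, int i, int j,
                                  const double* dx, double r, double dVdr) {
  double s = -dVdr / r;
  for (int d = 0; d < 3; ++d) {
    F(i, d) += s * dx[d];
    F(j, d) -= s * dx[d];
  }
}

static double energy_forces(const NumericMatrix& X, const BeadFF& f,
                            NumericMatrix& F) {
  const int n = X.nrow();
  double E = 0.0, dx[3];
  std::fill(F.begin(), F.end(), 0.0);

  // bonds (consecutive beads, harmonic about the virtual bond length)
  for (int i = 0; i + 1 < n; ++i) {
    double r = pair_dist(X, i, i + 1, dx);
    if (r < 1e-9) stop("overlapping bonded beads (r = 0).");
    double dr = r - f.bond_r0;
    E += 0.5 * f.bond_k * dr * dr;
    add_pair_force(F, i, i + 1, dx, r, f.bond_k * dr);
  }

  // angles (harmonic in theta)
  if (f.angle_k > 0) {
    for (int b = 1; b + 1 < n; ++b) {
      double u[3], v[3];
      double ru = pair_dist(X, b - 1, b, u);
      double rv = pair_dist(X, b + 1, b, v);
      double cth = (u[0] * v[0] + u[1] * v[1] + u[2] * v[2]) / (ru * rv);
      cth = std::max(-1.0, std::min(1.0, cth));
      double th = std::acos(cth);
      double sth = std::sqrt(std::max(1e-12, 1.0 - cth * cth));
      double dVdth = f.angle_k * (th - f.angle_theta0);
      E += 0.5 * f.angle_k * (th - f.angle_theta0) * (th - f.angle_theta0);
      // dtheta/da and dtheta/dc, with b the vertex
      for (int d = 0; d < 3; ++d) {
        double da = (cth * u[d] / ru - v[d] / rv) / (ru * sth);
        double dc = (cth * v[d] / rv - u[d] / ru) / (rv * sth);
        F(b - 1, d) -= dVdth * da;
        F(b + 1, d) -= dVdth * dc;
        F(b, d) += dVdth * (da + dc);
      }
    }
  }

  // non-bonded: repulsive r^-12 for pairs with sequence separation >= 3
  // that are not reference-structure contacts
  if (f.ev_eps > 0) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 3; j < n; ++j) {
        if (f.is_native[(size_t)i * n + j]) continue;
        double r = pair_dist(X, i, j, dx);
        if (r < 1e-9) stop("overlapping beads (r = 0).");
        double sr = f.ev_sigma / r;
        double sr6 = sr * sr * sr; sr6 *= sr6;
        double sr12 = sr6 * sr6;
        if (sr12 < 1e-10) continue; // negligible beyond ~2.2 sigma
        E += f.ev_eps * sr12;
        add_pair_force(F, i, j, dx, r, -12.0 * f.ev_eps * sr12 / r);
      }
    }
  }

  // structure-based 12-10 well at reference contact distances
  for (int c = 0; c < f.native.nrow(); ++c) {
    int i = f.native(c, 0) - 1, j = f.native(c, 1) - 1;
    double r = pair_dist(X, i, j, dx);
    if (r < 1e-9) stop("overlapping beads (r = 0).");
    double q = f.native_r[c] / r;
    double q2 = q * q, q10 = q2 * q2 * q2 * q2 * q2, q12 = q10 * q2;
    E += f.native_eps * (5.0 * q12 - 6.0 * q10);
    double dVdr = f.native_eps * (-60.0 * q12 + 60.0 * q10) / r;
    add_pair_force(F, i, j, dx, r, dVdr);
  }

  // sigmoid contact restraints (exact closed form, no interpolation)
  for (int c = 0; c < f.restraints.nrow(); ++c) {
    int i = f.restraints(c, 0) - 1, j = f.restraints(c, 1) - 1;
    double r = pair_dist(X, i, j, dx);
    double z = f.sg_alpha * (r - f.sg_r0);
    double p = 1.0 / (1.0 + std::exp(-std::fabs(z)));
    if (z < 0) p = 1.0 - p; // stable logistic
    E += f.sg_k * f.sg_A * p;
    add_pair_force(F, i, j, dx, r, f.sg_k * f.sg_A * f.sg_alpha * p * (1 - p));
  }
  return E;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix X, List ff) {
  BeadFF f = parse_ff(ff, X.nrow());
  NumericMatrix F(X.nrow(), 3);
  double E = energy_forces(X, f, F);
  return List::create(_["energy"] = E, _["forces"] = F);
}

// [[Rcpp::export]]
List cpp_langevin_run(NumericMatrix X0, NumericMatrix V0, List ff,
                      double temperature, double dt, double friction,
                      double mass, int n_steps, int sample_interval) {
  const int n = X0.nrow();
  NumericMatrix X = clone(X0), V = clone(V0), F(n, 3);
  BeadFF f = parse_ff(ff, n);
  RNGScope scope;

  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt((1.0 - c1 * c1) * KB * temperature / mass);
  if (friction == 0.0) { c1 = 1.0; c2 = 0.0; }

  double E = energy_forces(X, f, F);
  int n_samples = (sample_interval > 0) ? n_steps / sample_interval : 0;
  NumericVector frames((size_t)std::max(0, n_samples) * n * 3);
  NumericVector sampled_E(std::max(0, n_samples));
  NumericVector sampled_K(std::max(0, n_samples));
  int s = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) V(i, d) += 0.5 * dt * F(i, d) / mass;
    // A: half drift
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) X(i, d) += 0.5 * dt * V(i, d);
    // O: Ornstein-Uhlenbeck
    if (c2 > 0.0) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) V(i, d) = c1 * V(i, d) + c2 * norm_rand();
    }
    // A: half drift
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) X(i, d) += 0.5 * dt * V(i, d);
    // force update + B: half kick
    E = energy_forces(X, f, F);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) V(i, d) += 0.5 * dt * F(i, d) / mass;

    if (!std::isfinite(E)) stop("integration diverged; reduce dt.");
    if (sample_interval > 0 && step % sample_interval == 0) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          frames[(size_t)s * n * 3 + (size_t)i * 3 + d] = X(i, d);
      double K = 0.0;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) K += 0.5 * mass * V(i, d) * V(i, d);
      sampled_E[s] = E;
      sampled_K[s] = K;
      ++s;
    }
  }
  double bound = 1e4;
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d)
      if (std::fabs(X(i, d)) > bound) stop("integration diverged; reduce dt.");

  return List::create(_["coords"] = X, _["velocities"] = V,
                      _["energy"] = E, _["frames"] = frames,
                      _["sampled_energy"] = sampled_E,
                      _["sampled_kinetic"] = sampled_K,
                      _["n_samples"] = s);
}
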
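// Compiled kernels: pair potentials, forces, Langevin propagation, dock sweep.
// Energies are in units of k_B*T0, lengths in Angstroms, time in ps.
// All randomness comes from R's RNG so set.seed() on the R side gives
// bit-identical trajectories.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double R_GUARD = 1e-8; // singularity guard for coincident beads

static inline double morse(double r, double alpha, double l) {
  double e = std::exp(-alpha * (r - l));
  return e * e - 2.0 * e;
}

static inline double dmorse(double r, double alpha, double l) {
  double e = std::exp(-alpha * (r - l));
  return 2.0 * alpha * (e - e * e);
}

// Non-bonded pair potential. The r <= l branch carries the step value at
// r = l (half-open split), which makes U continuous with U(l) = eps_prime.
static inline double u_nonbonded(double r, double ep, double eps,
                                 double alpha, double l) {
  if (ep <= 0.0) {
    if (r <= l) return eps * morse(r, alpha, l) + (eps + ep);
    return -ep * morse(r, alpha, l);
  } else {
    double tail = ep * std::exp(-alpha * (r - l));
    if (r <= l) return eps * morse(r, alpha, l) + eps + tail;
    return tail;
  }
}

static inline double du_nonbonded(double r, double ep, double eps,
                                  double alpha, double l) {
  if (ep <= 0.0) {
    if (r <= l) return eps * dmorse(r, alpha, l);
    return -ep * dmorse(r, alpha, l);
  } else {
    double dtail = -alpha * ep * std::exp(-alpha * (r - l));
    if (r <= l) return eps * dmorse(r, alpha, l) + dtail;
    return dtail;
  }
}

// [[Rcpp::export]]
double cpp_nonbonded_energy(double r, double ep, double eps,
                            double alpha, double l) {
  return u_nonbonded(r, ep, eps, alpha, l);
}

// [[Rcpp::export]]
double cpp_total_energy(const NumericMatrix& X, const NumericMatrix& EP,
                        double kappa, double l, double eps, double alpha) {
  const int n = X.nrow();
  double u = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    double dx = X(i + 1, 0) - X(i, 0);
    double dy = X(i + 1, 1) - X(i, 1);
    double dz = X(i + 1, 2) - X(i, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    u += 0.5 * kappa * (r - l) * (r - l);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double dx = X(j, 0) - X(i, 0);
      double dy = X(j, 1) - X(i, 1);
      double dz = X(j, 2) - X(i, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      u += u_nonbonded(r, EP(i, j), eps, alpha, l);
    }
  }
  return u;
}

// Accumulate -dU/dx into F; returns number of guard events (r ~ 0).
static int forces_into(const NumericMatrix& X, const NumericMatrix& EP,
                       double kappa, double l, double eps, double alpha,
                       NumericMatrix& F) {
  const int n = X.nrow();
  int nguard = 0;
  std::fill(F.begin(), F.end(), 0.0);
  for (int i = 0; i + 1 < n; ++i) {
    double dx = X(i + 1, 0) - X(i, 0);
    double dy = X(i + 1, 1) - X(i, 1);
    double dz = X(i + 1, 2) - X(i, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < R_GUARD) { r = R_GUARD; ++nguard; dx = r; dy = 0; dz = 0; }
    double coef = -kappa * (r - l) / r; // force on j along (xj - xi)
    F(i + 1, 0) += coef * dx; F(i + 1, 1) += coef * dy; F(i + 1, 2) += coef * dz;
    F(i, 0) -= coef * dx;     F(i, 1) -= coef * dy;     F(i, 2) -= coef * dz;
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double dx = X(j, 0) - X(i, 0);
      double dy = X(j, 1) - X(i, 1);
      double dz = X(j, 2) - X(i, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < R_GUARD) { r = R_GUARD; ++nguard; dx = r; dy = 0; dz = 0; }
      double coef = -du_nonbonded(r, EP(i, j), eps, alpha, l) / r;
      F(j, 0) += coef * dx; F(j, 1) += coef * dy; F(j, 2) += coef * dz;
      F(i, 0) -= coef * dx; F(i, 1) -= coef * dy; F(i, 2) -= coef * dz;
    }
  }
  return nguard;
}

// [[Rcpp::export]]
List cpp_forces(const NumericMatrix& X, const NumericMatrix& EP,
                double kappa, double l, double eps, double alpha) {
  NumericMatrix F(X.nrow(), 3);
  int ng = forces_into(X, EP, kappa, l, eps, alpha, F);
  return List::create(_["F"] = F, _["n_guard"] = ng);
}

// BAOAB Langevin step sequence. mass in k_B*T0 * ps^2 / A^2, gamma in 1/ps,
// kT reduced (T/T0). sample_every > 0 stores position/velocity snapshots.
// [[Rcpp::export]]
List cpp_integrate(const NumericMatrix& X0, const NumericMatrix& V0,
                   const NumericMatrix& EP, double kappa, double l,
                   double eps, double alpha, double mass, double gamma,
                   double dt, double kT, int n_steps, int sample_every) {
  const int n = X0.nrow();
  NumericMatrix X = clone(X0), V = clone(V0), F(n, 3);
  int nguard = forces_into(X, EP, kappa, l, eps, alpha, F);
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * kT / mass);
  const double hdt = 0.5 * dt, hdtm = 0.5 * dt / mass;
  int n_samples = (sample_every > 0) ? n_steps / sample_every : 0;
  NumericMatrix SX(n_samples * n, 3), SV(n_samples * n, 3);
  int isample = 0;
  int bad_step = -1;
  RNGScope scope;
  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        V(i, k) += hdtm * F(i, k);
        X(i, k) += hdt * V(i, k);
      }
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        V(i, k) = c1 * V(i, k) + c2 * norm_rand();
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        X(i, k) += hdt * V(i, k);
    nguard += forces_into(X, EP, kappa, l, eps, alpha, F);
    bool ok = true;
    for (int i = 0; i < n && ok; ++i)
      for (int k = 0; k < 3; ++k)
        if (!std::isfinite(X(i, k)) || !std::isfinite(V(i, k))) { ok = false; break; }
    if (!ok) { bad_step = step + 1; break; }
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        V(i, k) += hdtm * F(i, k);
    if (sample_every > 0 && (step + 1) % sample_every == 0 && isample < n_samples) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) {
          SX(isample * n + i, k) = X(i, k);
          SV(isample * n + i, k) = V(i, k);
        }
      ++isample;
    }
  }
  return List::create(_["X"] = X, _["V"] = V, _["n_guard"] = nguard,
                      _["bad_step"] = bad_step,
                      _["sample_X"] = SX, _["sample_V"] = SV,
                      _["n_samples"] = isample);
}

// Shell-sweep dock of a single-monomer ligand. Points are unit vectors;
// shells are centered at `center` with the given radii. Site monomers
// attract via the unit Morse potential; all others contribute the
// excluded-volume core (left Morse branch shifted to zero at r = l),
// which is non-negative, i.e. purely repulsive.
// [[Rcpp::export]]
List cpp_dock(const NumericMatrix& X, const IntegerVector& site0,
              const NumericMatrix& pts, const NumericVector& radii,
              const NumericVector& center, double alpha, double l) {
  const int n = X.nrow(), npts = pts.nrow(), nrad = radii.size();
  std::vector<bool> in_site(n, false);
  for (int s = 0; s < site0.size(); ++s) in_site[site0[s]] = true;
  double best = R_PosInf, bx = NA_REAL, by = NA_REAL, bz = NA_REAL,
         brad = NA_REAL;
  for (int ir = 0; ir < nrad; ++ir) {
    double R = radii[ir];
    for (int ip = 0; ip < npts; ++ip) {
      double px = center[0] + R * pts(ip, 0);
      double py = center[1] + R * pts(ip, 1);
      double pz = center[2] + R * pts(ip, 2);
      double u = 0.0;
      for (int i = 0; i < n; ++i) {
        double dx = X(i, 0) - px, dy = X(i, 1) - py, dz = X(i, 2) - pz;
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (in_site[i]) {
          u += morse(r, alpha, l);
        } else if (r <= l) {
          u += morse(r, alpha, l) + 1.0;
        }
      }
      if (u < best) { best = u; bx = px; by = py; bz = pz; brad = R; }
    }
  }
  return List::create(_["position"] = NumericVector::create(bx, by, bz),
                      _["energy"] = best, _["shell_radius"] = brad);
}
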
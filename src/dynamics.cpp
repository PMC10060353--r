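#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise attractive-repulsive potential
//   U(r) = De * [1 - (phi(r)/phi(r0))^a]^2 - De
// with phi(r) = exp(-r)  (Morse, phi_kind = 0) or
//      phi(r) = 1/r      (Lennard-Jones shape, phi_kind = 1).
// Writing q(r) = (phi(r)/phi(r0))^a, all derivatives follow from q:
//   U'(r)  = -2 De (1 - q) q'
//   U''(r) =  2 De (q'^2 - (1 - q) q'')

static inline void pot_q(double r, double a, double r0, int phi_kind,
                         double &q, double &qp, double &qpp) {
  if (phi_kind == 0) {            // exponential decay
    q = std::exp(-a * (r - r0));
    qp = -a * q;
    qpp = a * a * q;
  } else {                        // reciprocal decay; r > 0 required
    q = std::pow(r0 / r, a);
    qp = -a * q / r;
    qpp = a * (a + 1.0) * q / (r * r);
  }
}

static inline double pot_U(double r, double De, double a, double r0,
                           int phi_kind) {
  double q, qp, qpp;
  pot_q(r, a, r0, phi_kind, q, qp, qpp);
  double b = 1.0 - q;
  return De * b * b - De;
}

static inline void pot_d1d2(double r, double De, double a, double r0,
                            int phi_kind, double &U1, double &U2) {
  double q, qp, qpp;
  pot_q(r, a, r0, phi_kind, q, qp, qpp);
  U1 = -2.0 * De * (1.0 - q) * qp;
  U2 = 2.0 * De * (qp * qp - (1.0 - q) * qpp);
}

// [[Rcpp::export]]
double cpp_potential(double r, double De, double a, double r0, int phi_kind) {
  return pot_U(r, De, a, r0, phi_kind);
}

// Drift a_i = -sum_{j != i} U'(r_ij) (x_i - x_j)/r_ij for every particle.
// [[Rcpp::export]]
NumericMatrix cpp_drift_all(NumericMatrix pos, double De, double a, double r0,
                            int phi_kind, double eps) {
  int n = pos.nrow();
  NumericMatrix drift(n, 2);
  if (De == 0.0) return drift;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double r = std::sqrt(dx * dx + dy * dy);
      if (r < eps)
        stop("degenerate geometry: particles %d and %d at distance %g (< %g)",
             i + 1, j + 1, r, eps);
      double U1, U2;
      pot_d1d2(r, De, a, r0, phi_kind, U1, U2);
      double fx = -U1 * dx / r;   // force on i from j
      double fy = -U1 * dy / r;
      drift(i, 0) += fx;
      drift(i, 1) += fy;
      drift(j, 0) -= fx;          // Newton's third law
      drift(j, 1) -= fy;
    }
  }
  return drift;
}

// Drift and drift-Jacobian A_i = -sum_{j != i} Hessian U(||x_i - x_j||)
// for every particle.  Hessian of a radial potential:
//   H = U''(r) u u^T + (U'(r)/r) (I - u u^T),  u = (x_i - x_j)/r.
// Returns list(drift = N x 2, jac = N x 4 as (a11, a12, a21, a22)).
// [[Rcpp::export]]
List cpp_drift_jac_all(NumericMatrix pos, double De, double a, double r0,
                       int phi_kind, double eps) {
  int n = pos.nrow();
  NumericMatrix drift(n, 2), jac(n, 4);
  if (De != 0.0) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = pos(i, 0) - pos(j, 0);
        double dy = pos(i, 1) - pos(j, 1);
        double r2 = dx * dx + dy * dy;
        double r = std::sqrt(r2);
        if (r < eps)
          stop("degenerate geometry: particles %d and %d at distance %g (< %g)",
               i + 1, j + 1, r, eps);
        double U1, U2;
        pot_d1d2(r, De, a, r0, phi_kind, U1, U2);
        double fx = -U1 * dx / r;
        double fy = -U1 * dy / r;
        drift(i, 0) += fx; drift(i, 1) += fy;
        drift(j, 0) -= fx; drift(j, 1) -= fy;
        // Hessian entries (same for both members of the pair: H depends on
        // the separation only through u u^T, which is even in the sign of u)
        double ux = dx / r, uy = dy / r;
        double rad = U2, tng = U1 / r;
        double h11 = rad * ux * ux + tng * (1.0 - ux * ux);
        double h12 = (rad - tng) * ux * uy;
        double h22 = rad * uy * uy + tng * (1.0 - uy * uy);
        jac(i, 0) -= h11; jac(i, 1) -= h12; jac(i, 2) -= h12; jac(i, 3) -= h22;
        jac(j, 0) -= h11; jac(j, 1) -= h12; jac(j, 2) -= h12; jac(j, 3) -= h22;
      }
    }
  }
  return List::create(_["drift"] = drift, _["jac"] = jac);
}

// Total interaction energy sum over unordered pairs (used in tests).
// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix pos, double De, double a, double r0,
                        int phi_kind, double eps) {
  int n = pos.nrow();
  double e = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double r = std::sqrt(dx * dx + dy * dy);
      if (r < eps)
        stop("degenerate geometry: particles %d and %d at distance %g (< %g)",
             i + 1, j + 1, r, eps);
      e += pot_U(r, De, a, r0, phi_kind);
    }
  return e;
}

// Reflect a coordinate into [0, L] (triangle-wave fold, handles any excursion).
static inline double reflect01(double x, double L) {
  if (x >= 0.0 && x <= L) return x;
  double period = 2.0 * L;
  x = std::fmod(x, period);
  if (x < 0.0) x += period;
  return (x > L) ? period - x : x;
}

// Euler-Maruyama integration of the interacting system:
//   x <- x + a(x) h + sigma_i sqrt(h) xi,   xi ~ N(0, I_2) per particle,
// reflecting walls at [0, box]^2 when box > 0.  Noise is drawn particle by
// particle in index order each step, using R's RNG (reproducible under
// set.seed).  Positions are recorded every `record_every` steps, starting
// with the initial state.  Returns an N x (K+1) x 2 array.
// [[Rcpp::export]]
NumericVector cpp_simulate(NumericMatrix pos0, NumericVector sigma, double De,
                           double a, double r0, int phi_kind, double h,
                           int n_steps, int record_every, double box,
                           double eps) {
  int n = pos0.nrow();
  int n_rec = n_steps / record_every + 1;
  NumericVector out(Dimension(n, n_rec, 2));
  NumericMatrix pos(clone(pos0));
  double sqh = std::sqrt(h);

  for (int i = 0; i < n; ++i) {
    out[i] = pos(i, 0);
    out[i + (long)n * n_rec] = pos(i, 1);
  }
  int rec = 1;
  for (int s = 1; s <= n_steps; ++s) {
    NumericMatrix drift = cpp_drift_all(pos, De, a, r0, phi_kind, eps);
    for (int i = 0; i < n; ++i) {
      double nx = norm_rand();
      double ny = norm_rand();
      double x = pos(i, 0) + drift(i, 0) * h + sigma[i] * sqh * nx;
      double y = pos(i, 1) + drift(i, 1) * h + sigma[i] * sqh * ny;
      if (box > 0.0) {
        x = reflect01(x, box);
        y = reflect01(y, box);
      }
      if (!std::isfinite(x) || !std::isfinite(y))
        stop("integration failure: non-finite position for particle %d at step %d",
             i + 1, s);
      pos(i, 0) = x;
      pos(i, 1) = y;
    }
    if (s % record_every == 0) {
      for (int i = 0; i < n; ++i) {
        out[i + (long)n * rec] = pos(i, 0);
        out[i + (long)n * (rec + n_rec)] = pos(i, 1);
      }
      ++rec;
    }
  }
  return out;
}
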
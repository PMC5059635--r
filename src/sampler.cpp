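#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Piecewise-linear interpolation of the tabulated potential.
// Outside the grid the potential is treated as +Inf (hard wall).
static inline double interp_u(double z, double lo, double dz,
                              const NumericVector &u, int n) {
  double x = (z - lo) / dz;
  if (x < 0.0 || x > n - 1) return R_PosInf;
  int i = (int)std::floor(x);
  if (i >= n - 1) return u[n - 1];
  double t = x - i;
  return u[i] * (1.0 - t) + u[i + 1] * t;
}

static inline double grad_u(double z, double lo, double dz,
                            const NumericVector &u, int n) {
  double x = (z - lo) / dz;
  int i = (int)std::floor(x);
  if (i < 0) i = 0;
  if (i > n - 2) i = n - 2;
  return (u[i + 1] - u[i]) / dz;
}

// Biased 1-D sampler on a tabulated potential plus a harmonic window bias
//   U(z) = u(z) + half_factor * k * (z - z0)^2
// scheme 0: random-walk Metropolis, proposal N(z, 2 D dt)  (exact stationary law)
// scheme 1: uncorrected overdamped Langevin (Euler-Maruyama), reflected at the
//           domain edges; errors out if the walker leaves the domain by > 5 A.
// Uses R's RNG so set.seed() in R gives bit-identical trajectories.
// [[Rcpp::export(name = ".sampler_cpp")]]
NumericVector sampler_cpp(int n_steps, int stride, double z_init,
                          double grid_lo, double grid_dz, NumericVector ugrid,
                          double bias_center, double bias_k, double half_factor,
                          double kT, double dt, double D, int scheme) {
  int n = ugrid.size();
  double z_lo = grid_lo;
  double z_hi = grid_lo + grid_dz * (n - 1);
  double sd = std::sqrt(2.0 * D * dt);
  int n_out = n_steps / stride;
  NumericVector out(n_out);
  double z = z_init;
  double U = interp_u(z, grid_lo, grid_dz, ugrid, n) +
             half_factor * bias_k * (z - bias_center) * (z - bias_center);
  int j = 0;
  RNGScope scope;
  for (int s = 1; s <= n_steps; ++s) {
    if (scheme == 0) {
      double zp = z + norm_rand() * sd;
      double Up = interp_u(zp, grid_lo, grid_dz, ugrid, n) +
                  half_factor * bias_k * (zp - bias_center) * (zp - bias_center);
      if (R_finite(Up)) {
        double dU = Up - U;
        if (dU <= 0.0 || unif_rand() < std::exp(-dU / kT)) {
          z = zp;
          U = Up;
        }
      }
    } else {
      double F = -(grad_u(z, grid_lo, grid_dz, ugrid, n) +
                   2.0 * half_factor * bias_k * (z - bias_center));
      z += dt * D * F / kT + norm_rand() * sd;
      if (z < z_lo - 5.0 || z > z_hi + 5.0 || !R_finite(z))
        stop("trajectory left the potential domain by more than 5 Angstrom; "
             "use a smaller time step (dt) or the metropolis scheme");
      if (z < z_lo) z = 2.0 * z_lo - z;  // reflect
      if (z > z_hi) z = 2.0 * z_hi - z;
      if (z < z_lo) z = z_lo;            // extreme overshoot after reflection
      if (z > z_hi) z = z_hi;
    }
    if (s % stride == 0 && j < n_out) out[j++] = z;
  }
  return out;
}
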
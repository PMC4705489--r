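#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Analytic reference surface G(xi, theta) in kcal/mol, xi in Angstrom,
// theta in degrees. Functional form: four bivariate Gaussian basins, an
// exponential repulsive wall at short range, a monotone long-range
// attraction shoulder, all multiplied by a C1 switch that takes the surface
// exactly to the plateau level beyond `switch_off`.

namespace {

struct Basin {
  double cx, ct, sx, st, depth;
};

struct Surface {
  std::vector<Basin> basins;
  double wall_x, wall_scale, wall_eps;
  double attr_depth, attr_on, attr_off;
  double switch_on, switch_off;
  double plateau;
};

Surface parse_surface(const List& sp) {
  Surface s;
  NumericMatrix b = sp["basins"];
  for (int i = 0; i < b.nrow(); ++i) {
    Basin bb = {b(i, 0), b(i, 1), b(i, 2), b(i, 3), b(i, 4)};
    s.basins.push_back(bb);
  }
  s.wall_x = as<double>(sp["wall_x"]);
  s.wall_scale = as<double>(sp["wall_scale"]);
  s.wall_eps = as<double>(sp["wall_eps"]);
  s.attr_depth = as<double>(sp["attr_depth"]);
  s.attr_on = as<double>(sp["attr_on"]);
  s.attr_off = as<double>(sp["attr_off"]);
  s.switch_on = as<double>(sp["switch_on"]);
  s.switch_off = as<double>(sp["switch_off"]);
  s.plateau = as<double>(sp["plateau"]);
  return s;
}

// C1 smoothstep on [0,1]
inline double sstep(double t) {
  if (t <= 0.0) return 0.0;
  if (t >= 1.0) return 1.0;
  return t * t * (3.0 - 2.0 * t);
}
inline double dsstep(double t) {
  if (t <= 0.0 || t >= 1.0) return 0.0;
  return 6.0 * t * (1.0 - t);
}

// core = wall + attraction + basins (before the plateau switch);
// fills d(core)/dxi and d(core)/dtheta
inline double core_energy(const Surface& s, double x, double t,
                          double& gx, double& gt) {
  double e = 0.0;
  gx = 0.0;
  gt = 0.0;

  // repulsive wall
  double w = s.wall_eps * std::exp(-(x - s.wall_x) / s.wall_scale);
  e += w;
  gx += -w / s.wall_scale;

  // attraction shoulder: -A for xi <= attr_on, rising smoothly to 0 at attr_off
  double span = s.attr_off - s.attr_on;
  double u = (x - s.attr_on) / span;
  double a = -s.attr_depth * (1.0 - sstep(u));
  e += a;
  gx += s.attr_depth * dsstep(u) / span;

  // basins
  for (size_t i = 0; i < s.basins.size(); ++i) {
    const Basin& b = s.basins[i];
    double zx = (x - b.cx) / b.sx;
    double zt = (t - b.ct) / b.st;
    double g = b.depth * std::exp(-0.5 * (zx * zx + zt * zt));
    e += g;
    gx += -g * zx / b.sx;
    gt += -g * zt / b.st;
  }
  return e;
}

inline double energy_grad(const Surface& s, double x, double t,
                          double& gx, double& gt) {
  double span = s.switch_off - s.switch_on;
  double u = (x - s.switch_on) / span;
  double S = 1.0 - sstep(u);
  if (S == 0.0) {
    gx = 0.0;
    gt = 0.0;
    return s.plateau;
  }
  double cgx, cgt;
  double core = core_energy(s, x, t, cgx, cgt);
  double dS = -dsstep(u) / span;
  gx = dS * core + S * cgx;
  gt = S * cgt;
  return s.plateau + S * core;
}

inline double reflect_into(double x, double lo, double hi) {
  // fold x into [lo, hi] by reflection
  double span = hi - lo;
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
    if (!std::isfinite(x)) break;
    (void)span;
  }
  return x;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_surface_energy(List sp, NumericVector xi, NumericVector theta) {
  Surface s = parse_surface(sp);
  int n = xi.size();
  NumericVector out(n);
  double gx, gt;
  for (int i = 0; i < n; ++i) out[i] = energy_grad(s, xi[i], theta[i], gx, gt);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_surface_grid(List sp, NumericVector xi, NumericVector theta) {
  Surface s = parse_surface(sp);
  int nx = xi.size(), nt = theta.size();
  NumericMatrix out(nx, nt);
  double gx, gt;
  for (int j = 0; j < nt; ++j)
    for (int i = 0; i < nx; ++i)
      out(i, j) = energy_grad(s, xi[i], theta[j], gx, gt);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_surface_gradient(List sp, NumericVector xi, NumericVector theta) {
  Surface s = parse_surface(sp);
  int n = xi.size();
  NumericMatrix out(n, 2);
  double gx, gt;
  for (int i = 0; i < n; ++i) {
    energy_grad(s, xi[i], theta[i], gx, gt);
    out(i, 0) = gx;
    out(i, 1) = gt;
  }
  return out;
}

// Overdamped Langevin on the surface plus a harmonic bias
// 0.5*k*(xi - c)^2 acting on xi only, integrated with the stochastic Heun
// (predictor-corrector) scheme: the Euler-Maruyama step predicts, the
// drift is then averaged between the two endpoints with the same noise.
// Weak order 2, so the stationary density is accurate at time steps where
// plain Euler-Maruyama is visibly biased.  Reflecting boundaries on both
// coordinates.  Uses R's RNG, so runs are reproducible via set.seed().
// [[Rcpp::export]]
NumericMatrix cpp_umbrella_bd(List sp, double beta, double d_xi, double d_theta,
                              double dt, int n_steps, int stride,
                              double bias_center, double bias_k,
                              double xi0, double theta0,
                              double xi_lo, double xi_hi) {
  Surface s = parse_surface(sp);
  int n_out = n_steps / stride;
  NumericMatrix out(n_out, 2);
  double x = xi0, t = theta0;
  const double nx = std::sqrt(2.0 * d_xi * dt);
  const double nt = std::sqrt(2.0 * d_theta * dt);
  const double max_dx = 0.25 * (xi_hi - xi_lo);
  double gx, gt, gx2, gt2;
  int k = 0;
  for (int step = 1; step <= n_steps; ++step) {
    energy_grad(s, x, t, gx, gt);
    gx += bias_k * (x - bias_center);
    double wx = nx * norm_rand();
    double wt = nt * norm_rand();
    // predictor (Euler-Maruyama)
    double xp = x - beta * d_xi * gx * dt + wx;
    double tp = t - beta * d_theta * gt * dt + wt;
    energy_grad(s, std::max(xp, xi_lo), std::min(std::max(tp, 0.0), 180.0),
                gx2, gt2);
    gx2 += bias_k * (xp - bias_center);
    double dx = -0.5 * beta * d_xi * (gx + gx2) * dt + wx;
    double dth = -0.5 * beta * d_theta * (gt + gt2) * dt + wt;
    if (std::fabs(dx) > max_dx)
      stop("unstable integration step: |d_xi| = %f A at step %d; reduce dt (currently %f)",
           std::fabs(dx), step, dt);
    x = reflect_into(x + dx, xi_lo, xi_hi);
    t = reflect_into(t + dth, 0.0, 180.0);
    if (step % stride == 0) {
      out(k, 0) = x;
      out(k, 1) = t;
      ++k;
    }
  }
  return out;
}

namespace {
// linear interpolation on a uniform grid with constant extrapolation
inline double lin_at(const NumericVector& v, double g0, double dg, double x) {
  double p = (x - g0) / dg;
  int n = v.size();
  if (p <= 0.0) return v[0];
  if (p >= n - 1) return v[n - 1];
  int i = (int)p;
  double f = p - i;
  return v[i] * (1.0 - f) + v[i + 1] * f;
}
}  // namespace

// First-passage times for 1D overdamped diffusion in effective potential U
// (supplied as force = -dU/dx on a uniform grid) with position-dependent D
// (linear interpolation; Ito convention with the dD/dx drift term).
// Returns one first-passage time per replica; NA for replicas hitting the
// step cap.
// [[Rcpp::export]]
NumericVector cpp_fpt(NumericVector force, NumericVector dvec,
                      double g0, double dg, double beta, double dt,
                      double x0, double absorbing, double reflecting,
                      int n_replicas, double max_steps) {
  NumericVector out(n_replicas);
  bool absorb_low = absorbing < reflecting;
  double lo = std::min(absorbing, reflecting);
  double hi = std::max(absorbing, reflecting);
  int n = dvec.size();
  for (int r = 0; r < n_replicas; ++r) {
    double x = x0;
    double steps = 0.0;
    bool done = false;
    while (steps < max_steps) {
      steps += 1.0;
      double D = lin_at(dvec, g0, dg, x);
      double F = lin_at(force, g0, dg, x);
      // local slope of D for the Ito spurious drift
      double p = (x - g0) / dg;
      double Dp = 0.0;
      if (p > 0.0 && p < n - 1) {
        int i = (int)p;
        Dp = (dvec[i + 1] - dvec[i]) / dg;
      }
      x += (beta * D * F + Dp) * dt + std::sqrt(2.0 * D * dt) * norm_rand();
      if (absorb_low) {
        if (x <= absorbing) { done = true; break; }
        if (x > hi) x = 2.0 * hi - x;
      } else {
        if (x >= absorbing) { done = true; break; }
        if (x < lo) x = 2.0 * lo - x;
      }
    }
    out[r] = done ? steps * dt : NA_REAL;
    if (r % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// 1D Brownian trajectory in a tabulated potential (force grid), constant
// D, stochastic Heun integration, reflecting boundaries at both grid ends.
// [[Rcpp::export]]
NumericVector cpp_traj1d(NumericVector force, double g0, double dg,
                         double beta, double d, double dt,
                         int n_steps, int stride, double x0) {
  int n = force.size();
  double lo = g0, hi = g0 + dg * (n - 1);
  int n_out = n_steps / stride;
  NumericVector out(n_out);
  double x = x0;
  const double nstep = std::sqrt(2.0 * d * dt);
  int k = 0;
  for (int step = 1; step <= n_steps; ++step) {
    double F = lin_at(force, g0, dg, x);
    double w = nstep * norm_rand();
    double xp = x + beta * d * F * dt + w;
    double F2 = lin_at(force, g0, dg, xp);
    x = reflect_into(x + 0.5 * beta * d * (F + F2) * dt + w, lo, hi);
    if (step % stride == 0) out[k++] = x;
  }
  return out;
}
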
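#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin rotor: d(phi) = -a*sin(phi)*dt + sqrt(2*D*dt)*xi.
// `a` = (1/2) alpha mu U l^2 / gamma (signed with U), D = effective rotational
// diffusion coefficient. Uses R's RNG so trajectories are reproducible with
// set.seed(). Records every `record_every`-th step, always including step 0.
// [[Rcpp::export]]
NumericVector bd_rotor(double phi0, int n_steps, double dt, double a, double D,
                       int record_every) {
  int n_rec = n_steps / record_every + 1;
  NumericVector out(n_rec);
  double phi = phi0;
  double sig = std::sqrt(2.0 * D * dt);
  out[0] = phi;
  int k = 1;
  for (int i = 1; i <= n_steps; ++i) {
    phi += -a * std::sin(phi) * dt + sig * norm_rand();
    if (i % record_every == 0) out[k++] = phi;
  }
  return out;
}

// Thinned stationary sampler: advances `burn` steps, then emits `n_samples`
// values spaced `lag` steps apart. Same dynamics as bd_rotor; avoids
// materialising the full trajectory for long equilibrium runs.
// [[Rcpp::export]]
NumericVector bd_rotor_thin(double phi0, int burn, int n_samples, int lag,
                            double dt, double a, double D) {
  NumericVector out(n_samples);
  double phi = phi0;
  double sig = std::sqrt(2.0 * D * dt);
  for (int i = 0; i < burn; ++i)
    phi += -a * std::sin(phi) * dt + sig * norm_rand();
  for (int s = 0; s < n_samples; ++s) {
    for (int i = 0; i < lag; ++i)
      phi += -a * std::sin(phi) * dt + sig * norm_rand();
    out[s] = phi;
  }
  return out;
}

// Two-degree-of-freedom Brownian dynamics on the upper hemisphere with
// potential E(theta, phi)/gamma = -b sin(theta) cos(phi) and isotropic
// rotational diffusion D. Spherical Laplacian gives the cot(theta) metric
// drift. Wall at theta = pi/2 and the pole are handled by reflection.
// Returns a 2-column matrix (theta, phi) at recorded steps.
// [[Rcpp::export]]
NumericMatrix bd_spherical(double theta0, double phi0, int n_steps, double dt,
                           double b, double D, int record_every) {
  int n_rec = n_steps / record_every + 1;
  NumericMatrix out(n_rec, 2);
  double th = theta0, ph = phi0;
  double sig = std::sqrt(2.0 * D * dt);
  const double half_pi = M_PI / 2.0, eps = 1e-6;
  out(0, 0) = th;
  out(0, 1) = ph;
  int k = 1;
  for (int i = 1; i <= n_steps; ++i) {
    double st = std::sin(th);
    if (st < eps) st = eps;
    double drift_th = D / std::tan(th) + b * std::cos(th) * std::cos(ph);
    double drift_ph = -b * std::sin(ph) / st;
    th += drift_th * dt + sig * norm_rand();
    ph += drift_ph * dt + (sig / st) * norm_rand();
    if (th < eps) th = 2.0 * eps - th;            // pole reflection
    if (th > half_pi) th = 2.0 * half_pi - th;    // wall reflection
    if (i % record_every == 0) {
      out(k, 0) = th;
      out(k, 1) = ph;
      ++k;
    }
  }
  return out;
}

// For each query point, does any reference point lie within `radius`
// (Euclidean)? Uniform-grid spatial hash; cell edge = radius, so only the
// 3x3 neighbourhood needs scanning.
// [[Rcpp::export]]
LogicalVector has_neighbor_within(NumericVector qx, NumericVector qy,
                                  NumericVector rx, NumericVector ry,
                                  double radius) {
  int nq = qx.size(), nr = rx.size();
  LogicalVector out(nq);
  if (nr == 0) return out;
  double x0 = *std::min_element(rx.begin(), rx.end());
  double y0 = *std::min_element(ry.begin(), ry.end());
  double x1 = *std::max_element(rx.begin(), rx.end());
  double y1 = *std::max_element(ry.begin(), ry.end());
  int ncx = std::max(1, (int)std::floor((x1 - x0) / radius) + 1);
  int ncy = std::max(1, (int)std::floor((y1 - y0) / radius) + 1);
  std::vector<std::vector<int> > grid((size_t)ncx * ncy);
  for (int j = 0; j < nr; ++j) {
    int cx = std::min(ncx - 1, std::max(0, (int)std::floor((rx[j] - x0) / radius)));
    int cy = std::min(ncy - 1, std::max(0, (int)std::floor((ry[j] - y0) / radius)));
    grid[(size_t)cx * ncy + cy].push_back(j);
  }
  double r2 = radius * radius;
  for (int i = 0; i < nq; ++i) {
    int cx = (int)std::floor((qx[i] - x0) / radius);
    int cy = (int)std::floor((qy[i] - y0) / radius);
    bool found = false;
    for (int dx = -1; dx <= 1 && !found; ++dx) {
      int gx = cx + dx;
      if (gx < 0 || gx >= ncx) continue;
      for (int dy = -1; dy <= 1 && !found; ++dy) {
        int gy = cy + dy;
        if (gy < 0 || gy >= ncy) continue;
        const std::vector<int> &cell = grid[(size_t)gx * ncy + gy];
        for (size_t m = 0; m < cell.size(); ++m) {
          double ddx = qx[i] - rx[cell[m]];
          double ddy = qy[i] - ry[cell[m]];
          if (ddx * ddx + ddy * ddy <= r2) { found = true; break; }
        }
      }
    }
    out[i] = found;
  }
  return out;
}
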
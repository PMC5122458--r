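#include <Rcpp.h>
using namespace Rcpp;

static inline double wrap_pi(double th) {
  // floor-based wrap to (-pi, pi] (avoids fmod for glibc portability)
  th -= 2.0 * M_PI * std::floor((th + M_PI) / (2.0 * M_PI));
  if (th <= -M_PI) th += 2.0 * M_PI;
  if (th > M_PI) th -= 2.0 * M_PI;
  return th;
}

// Euler-Maruyama integration of the heading SDEs on the circle.
// model 0: deterministic steering  d_theta = eps*cos(theta) dt + sqrt(2 dr) dW
// model 1: stochastic modulation   d_theta = sqrt(2 dr (1 - eps*sin(theta))) dW  (Ito)
// Saves theta every save_every steps (including the initial state).
// [[Rcpp::export]]
NumericMatrix sim_angles_cpp(int model, NumericVector theta0, double eps,
                             double dr, double dt, int nsteps,
                             int save_every) {
  int n = theta0.size();
  int nsave = nsteps / save_every + 1;
  NumericMatrix out(n, nsave);
  double s2d = std::sqrt(2.0 * dr * dt);
  std::vector<double> th(theta0.begin(), theta0.end());
  for (int i = 0; i < n; ++i) out(i, 0) = wrap_pi(th[i]);
  int k = 1;
  for (int s = 1; s <= nsteps; ++s) {
    for (int i = 0; i < n; ++i) {
      double z = norm_rand();
      if (model == 0) {
        th[i] += eps * std::cos(th[i]) * dt + s2d * z;
      } else {
        double amp2 = 1.0 - eps * std::sin(th[i]);
        if (amp2 < 0.0) amp2 = 0.0;
        th[i] += std::sqrt(2.0 * dr * amp2 * dt) * z;
      }
      th[i] = wrap_pi(th[i]);
    }
    if (s % save_every == 0) {
      for (int i = 0; i < n; ++i) out(i, k) = th[i];
      ++k;
    }
  }
  return out;
}

// Implicit (backward-Euler) upwind finite-volume step for the 1D
// Keller-Segel equation with no-flux walls. Vface has ny+1 rows (boundary
// faces are forced to zero flux) and one column per stored concentration
// frame at times tc; V is interpolated linearly in time. Mass is conserved
// exactly by construction. Returns rho at every save_every-th step
// (including the initial condition).
// [[Rcpp::export]]
NumericMatrix ks_solve_cpp(NumericVector rho0, double dy, double dt,
                           int nsteps, double D, NumericMatrix Vface,
                           NumericVector tc, int save_every) {
  int ny = rho0.size();
  if (Vface.nrow() != ny + 1) stop("Vface must have ny + 1 rows");
  int ntc = tc.size();
  int nsave = nsteps / save_every + 1;
  NumericMatrix out(ny, nsave);
  std::vector<double> rho(rho0.begin(), rho0.end());
  for (int i = 0; i < ny; ++i) out(i, 0) = rho[i];

  std::vector<double> a(ny), b(ny), c(ny), d(ny), V(ny + 1);
  std::vector<double> cp(ny), dp(ny);
  double r = dt / dy, g = D / dy;
  int k = 1;
  for (int s = 1; s <= nsteps; ++s) {
    double t = s * dt;
    // interpolate face velocities in time
    int j = 0;
    while (j < ntc - 1 && tc[j + 1] < t) ++j;
    double w = 0.0;
    if (ntc > 1 && j < ntc - 1) {
      w = (t - tc[j]) / (tc[j + 1] - tc[j]);
      if (w < 0) w = 0; if (w > 1) w = 1;
    }
    V[0] = 0.0; V[ny] = 0.0;
    for (int f = 1; f < ny; ++f) {
      double v0 = Vface(f, j);
      double v1 = (ntc > 1 && j < ntc - 1) ? Vface(f, j + 1) : v0;
      V[f] = (1.0 - w) * v0 + w * v1;
    }
    for (int i = 0; i < ny; ++i) {
      double vl = V[i], vr = V[i + 1];
      double vlp = vl > 0 ? vl : 0, vlm = vl < 0 ? vl : 0;
      double vrp = vr > 0 ? vr : 0, vrm = vr < 0 ? vr : 0;
      bool li = i > 0, ri = i < ny - 1;
      b[i] = 1.0 + r * ((ri ? vrp + g : 0.0) + (li ? -vlm + g : 0.0));
      a[i] = li ? -r * (vlp + g) : 0.0;
      c[i] = ri ? r * (vrm - g) : 0.0;
      d[i] = rho[i];
    }
    // Thomas algorithm
    cp[0] = c[0] / b[0];
    dp[0] = d[0] / b[0];
    for (int i = 1; i < ny; ++i) {
      double m = b[i] - a[i] * cp[i - 1];
      cp[i] = c[i] / m;
      dp[i] = (d[i] - a[i] * dp[i - 1]) / m;
    }
    rho[ny - 1] = dp[ny - 1];
    for (int i = ny - 2; i >= 0; --i) rho[i] = dp[i] - cp[i] * rho[i + 1];

    if (s % save_every == 0) {
      for (int i = 0; i < ny; ++i) out(i, k) = rho[i];
      ++k;
    }
  }
  return out;
}

// Biased swimmer trajectories: positions integrate dx = v (cos, sin) theta dt,
// heading follows the stochastic (rotational-diffusion modulation) strategy
// with a signed local bias eps(y, t) interpolated bilinearly from a grid.
// Walls reflect positions and headings specularly. Saves every save_every
// steps including the initial state.
// [[Rcpp::export]]
List generate_tracks_cpp(NumericVector x0, NumericVector y0,
                         NumericVector theta0, double v, double dr,
                         double dt, int nsteps, int save_every,
                         NumericMatrix bias, NumericVector ygrid,
                         NumericVector tgrid, double ymin, double ymax,
                         double xmin, double xmax) {
  int n = x0.size();
  int nyg = ygrid.size(), ntg = tgrid.size();
  if (bias.nrow() != nyg || bias.ncol() != ntg) stop("bias grid mismatch");
  int nsave = nsteps / save_every + 1;
  NumericMatrix X(n, nsave), Y(n, nsave), TH(n, nsave);
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end()),
      th(theta0.begin(), theta0.end());
  for (int i = 0; i < n; ++i) { X(i,0)=x[i]; Y(i,0)=y[i]; TH(i,0)=wrap_pi(th[i]); }
  double y0g = ygrid[0], dyg = nyg > 1 ? ygrid[1] - ygrid[0] : 1.0;
  int k = 1;
  for (int s = 1; s <= nsteps; ++s) {
    double t = (s - 1) * dt;
    // time bracket
    int jt = 0;
    while (jt < ntg - 1 && tgrid[jt + 1] < t) ++jt;
    double wt = 0.0;
    if (ntg > 1 && jt < ntg - 1) {
      wt = (t - tgrid[jt]) / (tgrid[jt + 1] - tgrid[jt]);
      if (wt < 0) wt = 0; if (wt > 1) wt = 1;
    }
    for (int i = 0; i < n; ++i) {
      // bilinear bias lookup
      double fy = (y[i] - y0g) / dyg;
      int iy = (int)std::floor(fy);
      if (iy < 0) iy = 0;
      if (iy > nyg - 2) iy = nyg - 2;
      double wy = fy - iy;
      if (wy < 0) wy = 0; if (wy > 1) wy = 1;
      double b0 = (1 - wy) * bias(iy, jt) + wy * bias(iy + 1, jt);
      double b1 = b0;
      if (ntg > 1 && jt < ntg - 1)
        b1 = (1 - wy) * bias(iy, jt + 1) + wy * bias(iy + 1, jt + 1);
      double eps = (1 - wt) * b0 + wt * b1;
      if (eps > 0.999) eps = 0.999;
      if (eps < -0.999) eps = -0.999;

      double amp2 = 1.0 - eps * std::sin(th[i]);
      if (amp2 < 0.0) amp2 = 0.0;
      th[i] = wrap_pi(th[i] + std::sqrt(2.0 * dr * amp2 * dt) * norm_rand());
      x[i] += v * std::cos(th[i]) * dt;
      y[i] += v * std::sin(th[i]) * dt;
      if (y[i] > ymax) { y[i] = 2 * ymax - y[i]; th[i] = wrap_pi(-th[i]); }
      if (y[i] < ymin) { y[i] = 2 * ymin - y[i]; th[i] = wrap_pi(-th[i]); }
      if (x[i] > xmax) { x[i] = 2 * xmax - x[i]; th[i] = wrap_pi(M_PI - th[i]); }
      if (x[i] < xmin) { x[i] = 2 * xmin - x[i]; th[i] = wrap_pi(M_PI - th[i]); }
    }
    if (s % save_every == 0) {
      for (int i = 0; i < n; ++i) { X(i,k)=x[i]; Y(i,k)=y[i]; TH(i,k)=th[i]; }
      ++k;
    }
  }
  return List::create(_["x"] = X, _["y"] = Y, _["theta"] = TH);
}
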
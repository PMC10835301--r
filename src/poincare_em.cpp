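#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of N Poincare oscillators with twist,
// mean-field coupling through the x coordinates and optional additive
// forcing on the y coordinates.
//
// State update per step (Ito/EM convention), for oscillator i with
// r_i = sqrt(x_i^2 + y_i^2) and omega_i = 2*pi/tau_i + eps*(A - r_i):
//   x_i <- x_i + [lambda*x_i*(A - r_i) - y_i*omega_i + Kc*M] * dt
//              + sigma_x*sqrt(dt)*xi
//   y_i <- y_i + [lambda*y_i*(A - r_i) + x_i*omega_i + Kttfl*drive] * dt
//              + sigma_y*sqrt(dt)*xi'
// M is the instantaneous mean of the x coordinates (recomputed every step).
//
// Noise uses R's RNG (seed via set.seed before the call): at each step the
// N x-increments are drawn first, then the N y-increments, matching the
// coordinate-ordered draws of the generic R-level integrator so the two
// paths agree to numerical precision under the same seed.
//
// drive: forcing value at the START of each step; length nsteps, or length
// 0 when Kttfl == 0.
// [[Rcpp::export]]
List poincare_em_cpp(NumericVector x0, NumericVector y0, NumericVector tau,
                     double A, double lambda, double eps,
                     double sigma_x, double sigma_y,
                     double Kc, double Kttfl, NumericVector drive,
                     double dt, int nsteps, int stride) {
  const int N = x0.size();
  if (tau.size() != N || y0.size() != N)
    stop("x0, y0 and tau must have the same length");
  if (dt <= 0) stop("dt must be > 0");
  if (stride < 1) stop("record_stride must be >= 1");
  if (Kttfl != 0.0 && drive.size() < nsteps)
    stop("drive series shorter than the number of integration steps");

  const int nrec = nsteps / stride + 1;
  NumericMatrix xr(N, nrec), yr(N, nrec);
  NumericVector times(nrec);

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> nx(N), ny(N);
  const double sdt = std::sqrt(dt);
  const double twopi = 2.0 * M_PI;

  for (int i = 0; i < N; ++i) { xr(i, 0) = x[i]; yr(i, 0) = y[i]; }
  times[0] = 0.0;

  int rec = 1;
  for (int s = 0; s < nsteps; ++s) {
    double M = 0.0;
    for (int i = 0; i < N; ++i) M += x[i];
    M /= N;
    const double force = (Kttfl != 0.0) ? Kttfl * drive[s] : 0.0;

    if (sigma_x > 0 || sigma_y > 0) {
      for (int i = 0; i < N; ++i) nx[i] = norm_rand();
      for (int i = 0; i < N; ++i) ny[i] = norm_rand();
    }

    for (int i = 0; i < N; ++i) {
      const double r = std::sqrt(x[i] * x[i] + y[i] * y[i]);
      const double rel = A - r;
      const double omega = twopi / tau[i] + eps * rel;
      const double dx = lambda * x[i] * rel - y[i] * omega + Kc * M;
      const double dy = lambda * y[i] * rel + x[i] * omega + force;
      x[i] += dx * dt;
      y[i] += dy * dt;
      if (sigma_x > 0 || sigma_y > 0) {
        x[i] += sigma_x * sdt * nx[i];
        y[i] += sigma_y * sdt * ny[i];
      }
    }

    if ((s + 1) % stride == 0) {
      for (int i = 0; i < N; ++i) {
        if (!std::isfinite(x[i]) || !std::isfinite(y[i]))
          stop("non-finite state at integration step %d (oscillator %d)",
               s + 1, i + 1);
        xr(i, rec) = x[i];
        yr(i, rec) = y[i];
      }
      times[rec] = (s + 1) * dt;
      ++rec;
    }
  }

  return List::create(_["times"] = times, _["x"] = xr, _["y"] = yr);
}
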
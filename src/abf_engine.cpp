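#include <Rcpp.h>
using namespace Rcpp;

// One adaptive-biasing-force window: overdamped Langevin dynamics on a 1-D
// bending coordinate theta (degrees), with the system force supplied as a
// lookup table (uniform grid, linear interpolation). Instantaneous forces are
// accumulated into fixed-width bins inside [lo, hi); the adaptive bias is the
// negated running mean force in the current bin, ramped linearly with the
// number of samples collected in that bin up to ramp_samples. Harmonic wall
// forces confine the walker to the window. Uses R's RNG so seeded runs are
// reproducible via set.seed().
// [[Rcpp::export(name = ".abf_window")]]
List abf_window(double theta0, double lo, double hi, double bin_w,
                double grid_x0, double grid_dx, NumericVector grid_force,
                int n_steps, double dt, double friction, double kT,
                double wall_k, int ramp_samples,
                NumericVector fsum_init, NumericVector count_init) {
  const int nbins = fsum_init.size();
  NumericVector fsum = clone(fsum_init);
  NumericVector count = clone(count_init);
  const int ng = grid_force.size();
  const double noise_sd = std::sqrt(2.0 * kT * dt / friction);
  double theta = theta0;

  RNGScope scope;
  for (int s = 0; s < n_steps; ++s) {
    double F = 0.0;
    // system force by linear interpolation on the tabulated gradient
    double u = (theta - grid_x0) / grid_dx;
    int i0 = (int)std::floor(u);
    if (i0 < 0) i0 = 0;
    if (i0 > ng - 2) i0 = ng - 2;
    double w = u - i0;
    if (w < 0) w = 0; if (w > 1) w = 1;
    double Fsys = (1.0 - w) * grid_force[i0] + w * grid_force[i0 + 1];
    F += Fsys;

    if (theta >= lo && theta < hi) {
      int b = (int)std::floor((theta - lo) / bin_w);
      if (b >= nbins) b = nbins - 1;
      count[b] += 1.0;
      fsum[b] += Fsys;
      double ramp = count[b] / (double)ramp_samples;
      if (ramp > 1.0) ramp = 1.0;
      F -= ramp * (fsum[b] / count[b]);
    }
    if (theta < lo) F += wall_k * (lo - theta);
    if (theta > hi) F -= wall_k * (theta - hi);

    theta += (F / friction) * dt + noise_sd * norm_rand();
  }

  return List::create(_["fsum"] = fsum, _["count"] = count,
                      _["theta_final"] = theta);
}
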
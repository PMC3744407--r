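#include <Rcpp.h>
using namespace Rcpp;

// Inner loop of the PIF simulator.
//
// The linear noise subsystem (y, s, eta) is advanced with its exact one-step
// Gaussian transition: A2 is the 2x2 matrix exponential of the damped
// oscillator drift over dt, L2 the lower Cholesky factor of the one-step
// conditional covariance, a_ou / sd_ou the exact OU decay and innovation SD.
// The voltage integrates dv = (1 + y + eta) dt with a trapezoidal rule within
// the step; the threshold crossing time is refined by linear interpolation.
// Uses R's RNG so results are reproducible via set.seed().
// [[Rcpp::export]]
NumericVector simulate_pif_cpp(int n_spikes, int discard, double dt,
                               NumericMatrix A2, NumericMatrix L2,
                               double a_ou, double sd_ou,
                               double y0, double s0, double eta0,
                               double max_time) {
  NumericVector out(n_spikes);
  const double a11 = A2(0, 0), a12 = A2(0, 1), a21 = A2(1, 0), a22 = A2(1, 1);
  const double l11 = L2(0, 0), l21 = L2(1, 0), l22 = L2(1, 1);
  const bool harm = (l11 != 0.0 || y0 != 0.0 || s0 != 0.0);
  const bool ou = (sd_ou != 0.0 || eta0 != 0.0);

  double y = y0, s = s0, eta = eta0;
  double v = 0.0, t = 0.0;
  int emitted = 0, kept = 0;
  long step = 0;

  while (kept < n_spikes) {
    double yn = 0.0, sn = 0.0, etan = eta;
    if (harm) {
      double z1 = norm_rand(), z2 = norm_rand();
      yn = a11 * y + a12 * s + l11 * z1;
      sn = a21 * y + a22 * s + l21 * z1 + l22 * z2;
    }
    if (ou) etan = a_ou * eta + sd_ou * norm_rand();

    double drift = 1.0 + 0.5 * (y + yn) + 0.5 * (eta + etan);
    double vn = v + dt * drift;

    if (vn >= 1.0) {
      // weak noise: at most one crossing per step (dv per step << 1)
      double frac = (1.0 - v) / (vn - v);
      double t_spike = t + frac * dt;
      emitted++;
      if (emitted > discard) out[kept++] = t_spike;
      vn -= 1.0;
    }

    v = vn; y = yn; s = sn; eta = etan;
    t += dt;

    if (++step % 1048576 == 0) {
      if (!R_finite(v) || !R_finite(y) || !R_finite(eta))
        stop("simulation state became non-finite at t = %g", t);
      if (t > max_time)
        stop("simulation exceeded max_time = %g before emitting %d spikes",
             max_time, n_spikes);
      Rcpp::checkUserInterrupt();
    }
  }
  return out;
}

// Sample path of the noise subsystem alone (used to calibrate the spectral
// conventions: peak frequency, FWHM quality factor, OU autocorrelation).
// [[Rcpp::export]]
NumericMatrix noise_path_cpp(int n_steps, NumericMatrix A2, NumericMatrix L2,
                             double a_ou, double sd_ou,
                             double y0, double s0, double eta0) {
  NumericMatrix out(n_steps, 3);
  const double a11 = A2(0, 0), a12 = A2(0, 1), a21 = A2(1, 0), a22 = A2(1, 1);
  const double l11 = L2(0, 0), l21 = L2(1, 0), l22 = L2(1, 1);
  double y = y0, s = s0, eta = eta0;
  for (int i = 0; i < n_steps; i++) {
    double z1 = norm_rand(), z2 = norm_rand();
    double yn = a11 * y + a12 * s + l11 * z1;
    double sn = a21 * y + a22 * s + l21 * z1 + l22 * z2;
    eta = a_ou * eta + sd_ou * norm_rand();
    y = yn; s = sn;
    out(i, 0) = y; out(i, 1) = s; out(i, 2) = eta;
  }
  return out;
}
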
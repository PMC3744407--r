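# Shared helpers: a cached reference simulation, segment-based Monte-Carlo
# standard errors, local-maximum counting, and a spectral-shape estimator of
# the harmonic-noise peak frequency and FWHM quality factor.

.osc_cache <- new.env(parent = emptyenv())

# Reference weak-noise simulation reused across tests (w = 0.4, Q = 10,
# sigma_h = 0.05, sigma_ou = 0.02, tau_ou = 0.1; 1e5 ISIs, fixed seed).
shared_sim <- function() {
  if (is.null(.osc_cache$sim)) {
    p <- pif_params(w = 0.4, Q = 10, sigma_h = 0.05, sigma_ou = 0.02)
    .osc_cache$params <- p
    .osc_cache$sim <- simulate_pif(p, n_spikes = 1e5, seed = 101)
  }
  list(params = .osc_cache$params, train = .osc_cache$sim,
       isi = diff(.osc_cache$sim$time))
}

trapz_num <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# statistic and its SE from n_seg consecutive segments
segment_se <- function(x, stat, n_seg = 20) {
  len <- floor(length(x) / n_seg)
  vals <- vapply(seq_len(n_seg), function(i)
    stat(x[((i - 1) * len + 1):(i * len)]), numeric(1))
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(n_seg))
}

# local maxima of a curve, keeping peaks above frac of the global maximum
local_maxima <- function(x, y, frac = 0.05) {
  idx <- which(diff(sign(diff(y))) == -2) + 1
  x[idx[y[idx] > frac * max(y)]]
}

# Peak frequency and FWHM-based quality factor of the harmonic-noise
# spectrum: segment-averaged periodogram of a simulated noise path, fitted
# with the damped-oscillator spectral shape on a log scale, FWHM read off
# the fitted curve.
spectral_peak_q <- function(params, seed, n = 2^22, dt = 0.02, nseg = 2^16) {
  np <- simulate_noise_path(params, n, dt = dt, seed = seed)
  x <- np$y
  ns <- floor(length(x) / nseg)
  acc <- 0
  for (i in seq_len(ns))
    acc <- acc + Mod(stats::fft(x[((i - 1) * nseg + 1):(i * nseg)]))^2
  spec <- acc[1:(nseg / 2 + 1)] / ns
  freq <- (0:(nseg / 2)) / (nseg * dt)
  i0 <- which.max(spec)
  half <- spec[i0] / 2
  wdx <- range(which(spec > half & abs(seq_along(spec) - i0) < 200))
  g0 <- 2 * pi * max(freq[wdx[2]] - freq[wdx[1]], 2 / (nseg * dt))
  sel <- which(freq > 0.5 * freq[i0] & freq < 1.6 * freq[i0])
  df <- data.frame(om = 2 * pi * freq[sel], y = log(spec[sel]))
  om_pk0 <- 2 * pi * freq[i0]
  fit <- stats::nls(
    y ~ lc - log((om0^2 - om^2)^2 + g^2 * om^2), data = df,
    start = list(lc = log(spec[i0] * g0^2 * om_pk0^2), om0 = om_pk0, g = g0),
    control = stats::nls.control(warnOnly = TRUE))
  co <- stats::coef(fit)
  Sf <- function(om) exp(co[1]) / ((co[2]^2 - om^2)^2 + co[3]^2 * om^2)
  ompk <- sqrt(co[2]^2 - co[3]^2 / 2)
  smax <- Sf(ompk)
  lo <- stats::uniroot(function(o) Sf(o) - smax / 2, c(ompk / 3, ompk))$root
  hi <- stats::uniroot(function(o) Sf(o) - smax / 2, c(ompk, 3 * ompk))$root
  list(peak = ompk / (2 * pi), q_fwhm = ompk / (hi - lo))
}
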
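#' Spike train container
#'
#' A `spike_train` is a tibble with a single column `time` holding strictly
#' increasing spike times, plus attributes recording the time units
#' (`"canonical"` for mean-ISI units or `"seconds"`), and optionally the
#' generating [pif_params()] and RNG seed.
#'
#' @param times Numeric vector of strictly increasing spike times.
#' @param units `"canonical"` or `"seconds"`.
#' @param params Optional generating [pif_params()].
#' @param seed Optional integer seed used to generate the train.
#' @return A tibble of class `spike_train`.
#' @export
spike_train <- function(times, units = c("canonical", "seconds"),
                        params = NULL, seed = NULL) {
  units <- match.arg(units)
  times <- as.numeric(times)
  if (length(times) >= 2) {
    bad <- which(diff(times) <= 0)
    if (length(bad) > 0)
      stop(sprintf("spike times must be strictly increasing; first violation at index %d",
                   bad[1] + 1))
  }
  out <- tibble::tibble(time = times)
  attr(out, "units") <- units
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  class(out) <- c("spike_train", class(out))
  out
}

# Accept a spike_train, data frame with a time column, or bare numeric vector.
spike_times_of <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.data.frame(x)) {
    col <- if ("time" %in% names(x)) x[["time"]] else x[[1]]
    return(as.numeric(col))
  }
  stop("expected a spike_train, data frame, or numeric vector of spike times")
}

# Exact one-step Gaussian transition of the linear (y, s) oscillator
# subsystem over a step dt: the matrix exponential of the drift and the
# Cholesky factor of the conditional covariance Sigma_s - A Sigma_s A',
# where Sigma_s = diag(sigma_h^2, sigma_h^2 omega0^2) is the stationary
# covariance. Exactness here means the simulated noise path has the correct
# distribution at the grid points for any dt.
harmonic_step_matrices <- function(params, dt) {
  g <- params$gamma; w1 <- params$omega1; w0sq <- params$omega0^2
  e <- exp(-g * dt / 2)
  cw <- cos(w1 * dt); sw <- sin(w1 * dt)
  A <- matrix(c(
    e * (cw + g / (2 * w1) * sw), e * sw / w1,
    -e * w0sq * sw / w1,          e * (cw - g / (2 * w1) * sw)
  ), nrow = 2, byrow = TRUE)
  if (params$sigma_h == 0) {
    return(list(A = A, L = matrix(0, 2, 2)))
  }
  S_stat <- diag(c(params$sigma_h^2, params$sigma_h^2 * w0sq))
  S_cond <- S_stat - A %*% S_stat %*% t(A)
  S_cond <- (S_cond + t(S_cond)) / 2
  # guard tiny negative eigenvalues from cancellation at very small dt
  ev <- eigen(S_cond, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  Lfull <- ev$vectors %*% diag(sqrt(lam))
  # lower-triangularize via QR so the C++ loop can use (l11, l21, l22)
  qrL <- qr(t(Lfull))
  L <- t(qr.R(qrL))
  # fix signs so diagonal is non-negative
  sgn <- ifelse(diag(L) < 0, -1, 1)
  L <- L * rep(sgn, each = 2)
  list(A = A, L = L)
}

#' Simulate the PIF neuron driven by harmonic and OU noise
#'
#' Integrates the canonical model: voltage obeys `dv/dt = 1 + y + eta`, a
#' spike is emitted when `v` crosses 1, `v` is reset to 0, and the noise
#' state is untouched by the reset. The linear noise subsystem is advanced
#' with its exact one-step Gaussian transition (no discretization bias in the
#' noise statistics); the voltage uses a trapezoidal rule within the step and
#' the crossing time is refined by linear interpolation, so with zero noise
#' every interval equals exactly one canonical unit.
#'
#' @param params A [pif_params()] object.
#' @param n_spikes Number of spike times to return (after the discard).
#' @param dt Integration step in canonical units. Must satisfy
#'   `dt <= 1/(10*omega0)`; a warning is issued when `dt > tau_ou/10`.
#' @param seed Optional integer seed.
#' @param discard Number of initial spikes discarded as warm-up. The noise
#'   starts from its stationary law, so the warm-up only erases the `v = 0`
#'   phase condition at time zero.
#' @return A [spike_train()]; times are in seconds when `params$rate_hz` is
#'   set, otherwise in canonical units.
#' @examples
#' p <- pif_params(w = 0.4, Q = 10, sigma_h = 0.05, sigma_ou = 0.02)
#' st <- simulate_pif(p, n_spikes = 500, seed = 1)
#' mean(diff(st$time))  # close to 1 (canonical units)
#' @export
simulate_pif <- function(params, n_spikes, dt = 1 / 500, seed = NULL,
                         discard = 100) {
  params <- as_pif_params(params)
  stopifnot(n_spikes >= 1)
  if (dt > 1 / (10 * params$omega0))
    stop(sprintf("dt = %g too large: must be <= 1/(10*omega0) = %g",
                 dt, 1 / (10 * params$omega0)))
  if (dt > params$tau_ou / 10)
    warning("dt exceeds tau_ou/10; OU sample path is coarsely resolved ",
            "(its statistics remain exact at the grid points)")
  if (!is.null(seed)) set.seed(seed)

  init <- sample_stationary_noise_state(params, n = 1)
  mats <- harmonic_step_matrices(params, dt)
  a_ou <- exp(-dt / params$tau_ou)
  sd_ou <- params$sigma_ou * sqrt(1 - a_ou^2)
  # generous cap: weak noise keeps the rate near 1 per canonical unit
  max_time <- 10 * (n_spikes + discard + 100)

  times <- simulate_pif_cpp(as.integer(n_spikes), as.integer(discard), dt,
                            mats$A, mats$L, a_ou, sd_ou,
                            init$y, init$s, init$eta, max_time)
  if (!is.null(params$rate_hz)) {
    spike_train(times / params$rate_hz, units = "seconds",
                params = params, seed = seed)
  } else {
    spike_train(times, units = "canonical", params = params, seed = seed)
  }
}

#' Simulate a sample path of the noise subsystem
#'
#' Advances the harmonic-noise pair `(y, s)` and the OU variable `eta` alone
#' with the exact one-step Gaussian transition, starting from the stationary
#' law. Useful for calibrating the spectral conventions (peak frequency,
#' FWHM-based quality factor) and the stationary statistics of the noise.
#'
#' @param params A [pif_params()] object.
#' @param n_steps Number of steps.
#' @param dt Step size in canonical units.
#' @param seed Optional integer seed.
#' @return A tibble with columns `t`, `y`, `s`, `eta`.
#' @export
simulate_noise_path <- function(params, n_steps, dt = 1 / 100, seed = NULL) {
  params <- as_pif_params(params)
  stopifnot(n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  init <- sample_stationary_noise_state(params, n = 1)
  mats <- harmonic_step_matrices(params, dt)
  a_ou <- exp(-dt / params$tau_ou)
  sd_ou <- params$sigma_ou * sqrt(1 - a_ou^2)
  m <- noise_path_cpp(as.integer(n_steps), mats$A, mats$L, a_ou, sd_ou,
                      init$y, init$s, init$eta)
  tibble::tibble(t = seq_len(n_steps) * dt, y = m[, 1], s = m[, 2],
                 eta = m[, 3])
}
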
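#' Model parameters for the oscillation-driven integrate-and-fire neuron
#'
#' Constructs the canonical (nondimensional) parameter set of a perfect
#' integrate-and-fire (PIF) neuron whose input current is the sum of a
#' constant base current, Gaussian harmonic (narrow-band) noise, and a
#' broadband Ornstein-Uhlenbeck (OU) process. Time is measured in units of
#' the mean interspike interval (so the mean firing rate is 1) and voltage in
#' units of the threshold; physical units are restored through `rate_hz`.
#'
#' The harmonic noise is the stationary output of a noise-driven damped
#' harmonic oscillator with damped angular frequency `omega1 = 2*pi*w`,
#' damping `gamma = omega1 / Q` (so `Q` is the spectral peak frequency over
#' the full width at half maximum of the noise spectrum) and undamped
#' frequency `omega0 = sqrt(omega1^2 + gamma^2/4)`. Its stationary standard
#' deviation, relative to the base current, is `sigma_h`; the white-noise
#' intensity driving the oscillator is derived as
#' `D_h = sigma_h^2 * gamma * omega0^2`. The OU process has stationary SD
#' `sigma_ou`, correlation time `tau_ou` (in mean-ISI units) and intensity
#' `D_ou = sigma_ou^2 * tau_ou`.
#'
#' @param w Frequency ratio: harmonic-noise peak frequency over the neuron's
#'   mean firing rate. Must be positive.
#' @param Q Quality factor of the harmonic noise (peak frequency over
#'   bandwidth). Must be positive. Values `Q <= 1/2` describe an overdamped
#'   oscillator without a spectral peak; they are accepted by the simulator
#'   but rejected by the high-coherence closed-form statistics.
#' @param sigma_h Stationary SD of the harmonic noise relative to the base
#'   current (dimensionless, `>= 0`).
#' @param sigma_ou Stationary SD of the OU noise relative to the base current
#'   (dimensionless, `>= 0`).
#' @param tau_ou OU correlation time in units of the mean ISI (positive).
#' @param rate_hz Optional physical mean firing rate in Hz. When set, spike
#'   times produced by [simulate_pif()] are returned in seconds.
#'
#' @return An object of class `pif_params`: a list with the supplied fields
#'   plus the derived Langevin coefficients `omega1`, `gamma`, `omega0`,
#'   `D_h`, `D_ou` and the perturbation parameter `epsilon =
#'   sigma_h^2 + sigma_ou^2`.
#'
#' @examples
#' p <- pif_params(w = 0.408, Q = 16.40, sigma_h = 0.197, sigma_ou = 0.226)
#' p$gamma            # omega1 / Q
#' pif_epsilon(p)
#' @export
pif_params <- function(w, Q, sigma_h, sigma_ou, tau_ou = 0.1, rate_hz = NULL) {
  stopifnot(is.numeric(w), length(w) == 1, is.numeric(Q), length(Q) == 1)
  if (!is.finite(w) || w <= 0) stop("`w` must be a positive number")
  if (!is.finite(Q) || Q <= 0) stop("`Q` must be a positive number")
  if (!is.finite(sigma_h) || sigma_h < 0) stop("`sigma_h` must be >= 0")
  if (!is.finite(sigma_ou) || sigma_ou < 0) stop("`sigma_ou` must be >= 0")
  if (!is.finite(tau_ou) || tau_ou <= 0) stop("`tau_ou` must be positive")
  if (!is.null(rate_hz) && (!is.finite(rate_hz) || rate_hz <= 0))
    stop("`rate_hz` must be positive when given")

  omega1 <- 2 * pi * w
  gamma <- omega1 / Q
  omega0 <- sqrt(omega1^2 + gamma^2 / 4)
  structure(
    list(
      w = w, Q = Q, sigma_h = sigma_h, sigma_ou = sigma_ou,
      tau_ou = tau_ou, rate_hz = rate_hz,
      omega1 = omega1, gamma = gamma, omega0 = omega0,
      D_h = sigma_h^2 * gamma * omega0^2,
      D_ou = sigma_ou^2 * tau_ou,
      epsilon = sigma_h^2 + sigma_ou^2
    ),
    class = "pif_params"
  )
}

#' @export
print.pif_params <- function(x, ...) {
  cat("<pif_params>\n")
  cat(sprintf("  w = %.4g, Q = %.4g, sigma_h = %.4g, sigma_ou = %.4g, tau_ou = %.4g\n",
              x$w, x$Q, x$sigma_h, x$sigma_ou, x$tau_ou))
  cat(sprintf("  derived: omega1 = %.4g, gamma = %.4g, omega0 = %.4g, D_h = %.4g, D_ou = %.4g\n",
              x$omega1, x$gamma, x$omega0, x$D_h, x$D_ou))
  if (!is.null(x$rate_hz)) cat(sprintf("  rate_hz = %.4g\n", x$rate_hz))
  invisible(x)
}

as_pif_params <- function(x) {
  if (inherits(x, "pif_params")) return(x)
  if (is.list(x) || is.data.frame(x)) {
    x <- as.list(x)
    return(pif_params(
      w = x$w, Q = x$Q, sigma_h = x$sigma_h, sigma_ou = x$sigma_ou,
      tau_ou = if (is.null(x$tau_ou)) 0.1 else x$tau_ou,
      rate_hz = x$rate_hz
    ))
  }
  stop("cannot interpret `params`; supply a pif_params object")
}

#' Langevin coefficients of the harmonic noise
#'
#' Maps the spectral description of the stochastic oscillation (frequency
#' ratio `w`, quality factor `Q`, stationary SD `sigma_h`) to the
#' coefficients of the damped-oscillator Langevin pair: damping `gamma`,
#' undamped frequency `omega0`, damped frequency `omega1 = 2*pi*w` and the
#' driving white-noise intensity `D_h` chosen so that the stationary variance
#' of the oscillator position equals `sigma_h^2`.
#'
#' @inheritParams pif_params
#' @return A one-row tibble with columns `gamma`, `omega0`, `omega1`, `D_h`.
#' @seealso [harmonic_from_coefficients()] for the inverse map.
#' @examples
#' harmonic_coefficients(w = 0.408, Q = 16.40, sigma_h = 0.197)
#' @export
harmonic_coefficients <- function(w, Q, sigma_h) {
  if (!is.finite(w) || w <= 0) stop("`w` must be a positive number")
  if (!is.finite(Q) || Q <= 0) stop("`Q` must be a positive number")
  if (!is.finite(sigma_h) || sigma_h < 0) stop("`sigma_h` must be >= 0")
  omega1 <- 2 * pi * w
  gamma <- omega1 / Q
  omega0 <- sqrt(omega1^2 + gamma^2 / 4)
  tibble::tibble(gamma = gamma, omega0 = omega0, omega1 = omega1,
                 D_h = sigma_h^2 * gamma * omega0^2)
}

#' Spectral parameters from Langevin coefficients
#'
#' Inverse of [harmonic_coefficients()]: recovers `(w, Q, sigma_h)` from the
#' damped-oscillator coefficients `(gamma, omega0, D_h)`.
#'
#' @param gamma Damping coefficient (positive).
#' @param omega0 Undamped angular frequency; requires `omega0 > gamma/2` so
#'   that the oscillator is underdamped.
#' @param D_h Driving white-noise intensity (`>= 0`).
#' @return A one-row tibble with columns `w`, `Q`, `sigma_h`.
#' @export
harmonic_from_coefficients <- function(gamma, omega0, D_h) {
  if (!is.finite(gamma) || gamma <= 0) stop("`gamma` must be positive")
  if (!is.finite(omega0) || omega0 <= gamma / 2)
    stop("`omega0` must exceed gamma/2 (underdamped oscillator)")
  if (!is.finite(D_h) || D_h < 0) stop("`D_h` must be >= 0")
  omega1 <- sqrt(omega0^2 - gamma^2 / 4)
  tibble::tibble(w = omega1 / (2 * pi), Q = omega1 / gamma,
                 sigma_h = sqrt(D_h / (gamma * omega0^2)))
}

#' Perturbation parameter and validity of the weak-noise theory
#'
#' The closed-form ISI statistics are leading-order results in the total
#' noise variance `epsilon = sigma_h^2 + sigma_ou^2`. They are accurate as
#' long as the predicted coefficient of variation stays below about 0.3;
#' beyond that the returned `valid` flag is `FALSE`.
#'
#' @param params A [pif_params()] object.
#' @return A one-row tibble with columns `epsilon`, `cv_predicted`, `valid`.
#' @export
pif_epsilon <- function(params) {
  params <- as_pif_params(params)
  cv <- cv_theory(params, mode = "general")
  tibble::tibble(epsilon = params$epsilon, cv_predicted = cv, valid = cv <= 0.3)
}

#' Draw from the stationary law of the noise state
#'
#' Samples the joint stationary distribution of the harmonic-noise pair
#' (position `y`, velocity `s`) and the OU variable `eta`. In the stationary
#' state `y` and `s` are independent zero-mean Gaussians with variances
#' `sigma_h^2` and `sigma_h^2 * omega0^2`, and `eta` is Gaussian with SD
#' `sigma_ou`. The simulator starts from such a draw because the noise is not
#' reset at spikes: the ensemble entering a first-passage problem carries the
#' stationary noise law.
#'
#' @param params A [pif_params()] object.
#' @param n Number of independent draws.
#' @param seed Optional integer seed (applied with [set.seed()]).
#' @return A tibble with `n` rows and columns `y`, `s`, `eta`.
#' @export
sample_stationary_noise_state <- function(params, n = 1, seed = NULL) {
  params <- as_pif_params(params)
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    y = stats::rnorm(n, 0, params$sigma_h),
    s = stats::rnorm(n, 0, params$sigma_h * params$omega0),
    eta = stats::rnorm(n, 0, params$sigma_ou)
  )
}
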
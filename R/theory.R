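# Closed-form weak-noise ISI statistics.
#
# All results are leading-order in the total noise variance
# epsilon = sigma_h^2 + sigma_ou^2. The central object is the variance of the
# integrated input noise over a window of length T (equivalently, the
# variance of the n-th-order interval for T = n):
#
#   DeltaV(T) = 2 * int_0^T (T - t) C_z(t) dt,
#
# with C_z the stationary autocorrelation of the total noise z = y + eta.
# For the harmonic noise, C_y(t) = sigma_h^2 Re[(1 - i g/(2 w1)) e^{-lam t}]
# with lam = g/2 - i w1, which yields an elementary complex closed form; the
# OU part is exponential. Everything else (CV, serial correlations,
# correlation lag, ISI density) follows from DeltaV.

theory_complex_coefs <- function(params) {
  g <- params$gamma; w1 <- params$omega1
  list(
    lam = complex(real = g / 2, imaginary = -w1),
    alpha = params$sigma_h^2 * complex(real = 1, imaginary = -g / (2 * w1))
  )
}

check_simplified_window <- function(params, what) {
  if (params$Q < 5 || params$tau_ou > 0.2)
    stop(sprintf(paste0(
      "simplified %s requires a high-coherence, short-OU regime ",
      "(Q >= 5 and tau_ou <= 0.2); got Q = %.3g, tau_ou = %.3g. ",
      "Use mode = \"general\" (or \"full\") instead."),
      what, params$Q, params$tau_ou))
}

# Variance of the integrated noise over a window T (vectorized in T).
delta_v <- function(T, params, mode = c("general", "simplified")) {
  mode <- match.arg(mode)
  sh2 <- params$sigma_h^2; so2 <- params$sigma_ou^2
  tau <- params$tau_ou; g <- params$gamma; w1 <- params$omega1
  if (mode == "general") {
    cc <- theory_complex_coefs(params)
    harm <- if (sh2 > 0)
      2 * Re(cc$alpha * (T / cc$lam - (1 - exp(-cc$lam * T)) / cc$lam^2))
    else rep(0, length(T))
    ou <- 2 * so2 * tau * T - 2 * so2 * tau^2 * (1 - exp(-T / tau))
  } else {
    harm <- 2 * sh2 * (g * T + 1 - exp(-g * T / 2) * cos(w1 * T)) / w1^2
    ou <- 2 * so2 * tau * T
  }
  harm + ou
}

#' Variance of the n-th-order interval
#'
#' Leading-order variance of the sum of `n` consecutive ISIs (equal to the
#' `n`-th spike time when the origin is a spike), in canonical units. For
#' `n = 1` this is the squared coefficient of variation. In the white-noise
#' limit (`sigma_h = 0`, `tau_ou -> 0`) the variance grows linearly in `n`,
#' the renewal signature; the harmonic noise adds a damped oscillation.
#'
#' @param n Positive integer order(s); vectorized.
#' @param params A [pif_params()] object.
#' @param mode `"general"` (any Q, any tau_ou) or `"simplified"`
#'   (high-coherence, short-OU reduction).
#' @return Numeric vector of variances.
#' @export
nth_order_variance <- function(n, params, mode = c("general", "simplified")) {
  mode <- match.arg(mode)
  params <- as_pif_params(params)
  stopifnot(all(n >= 1))
  if (mode == "simplified") check_simplified_window(params, "nth_order_variance")
  delta_v(n, params, mode)
}

#' Coefficient of variation of the ISIs (closed form)
#'
#' Leading-order weak-noise CV. In `"simplified"` mode (high quality factor,
#' short OU correlation time) the squared CV is
#' `2*D_ou + 2*sigma_h^2*(gamma + 1 - exp(-gamma/2)*cos(omega1)) / omega1^2`:
#' the OU and harmonic contributions are additive, the CV oscillates in the
#' frequency ratio `w` with local minima near integer `w`, and declines
#' overall with `w`. `"general"` keeps the exact harmonic autocorrelation and
#' the finite-`tau_ou` OU correction.
#'
#' @inheritParams nth_order_variance
#' @return A single non-negative number.
#' @examples
#' p <- pif_params(w = 0.408, Q = 16.40, sigma_h = 0.197,
#'                 sigma_ou = sqrt(5.10e-3 / 0.1))
#' cv_theory(p, mode = "simplified")  # ~0.18
#' @export
cv_theory <- function(params, mode = c("general", "simplified")) {
  mode <- match.arg(mode)
  params <- as_pif_params(params)
  if (mode == "simplified" && (params$Q < 5 || params$tau_ou > 0.2))
    warning("simplified CV evaluated outside its validity window (Q >= 5, tau_ou <= 0.2)")
  sqrt(delta_v(1, params, mode))
}

# Complex amplitude of the harmonic part of the ISI covariance at lag k:
# Cov_h(k) = Re(beta * exp(-lam * k)), an exactly damped cosine in the lag.
scc_beta <- function(params) {
  cc <- theory_complex_coefs(params)
  cc$alpha * (exp(cc$lam) + exp(-cc$lam) - 2) / cc$lam^2
}

#' Lag-independent coefficients of the serial-correlation closed form
#'
#' The high-coherence serial correlation coefficient is a damped oscillation
#' sampled at integer lags,
#' `rho_k = amplitude * decay^k * cos(omega1 * k + phase)`, with the squared
#' CV in the denominator of the amplitude. The decay per lag is
#' `exp(-gamma/2) = exp(-pi*w/Q)`: serial correlations persist exactly as
#' long as the phase coherence of the driving oscillation.
#'
#' @param params A [pif_params()] object.
#' @param cv2 Squared CV used in the prefactor; defaults to the simplified
#'   closed form. Pass a measured squared CV to reproduce the fitting model.
#' @return A one-row tibble with columns `amplitude`, `phase`, `decay`,
#'   `omega1`, `cv2`.
#' @export
scc_coefficients <- function(params, cv2 = NULL) {
  params <- as_pif_params(params)
  if (is.null(cv2)) cv2 <- delta_v(1, params, "simplified")
  beta <- scc_beta(params)
  tibble::tibble(
    amplitude = Mod(beta) / cv2,
    phase = Arg(beta),
    decay = exp(-params$gamma / 2),
    omega1 = params$omega1,
    cv2 = cv2
  )
}

#' Serial correlation coefficients of the ISIs (closed form)
#'
#' Leading-order weak-noise serial correlation coefficient at integer lags
#' `k >= 1`. In `"simplified"` mode (high coherence, short OU) only the
#' harmonic noise contributes and `rho_k` is a damped cosine in the lag with
#' decay `exp(-pi*w/Q)` per lag; in `"general"` mode the finite-`tau_ou` OU
#' contribution (positive, decaying as `exp(-(k-1)/tau_ou)`) is included and
#' the exact leading-order CV normalizes the coefficients.
#'
#' @param k Vector of positive integer lags.
#' @inheritParams nth_order_variance
#' @param cv2 Optional squared CV for the prefactor (simplified mode only);
#'   defaults to the simplified closed form.
#' @return Numeric vector `rho_k`, same length as `k`.
#' @examples
#' p <- pif_params(w = 0.408, Q = 16.40, sigma_h = 0.197,
#'                 sigma_ou = sqrt(5.10e-3 / 0.1))
#' scc_theory(1:10, p, mode = "simplified")
#' @export
scc_theory <- function(k, params, mode = c("general", "simplified"), cv2 = NULL) {
  mode <- match.arg(mode)
  params <- as_pif_params(params)
  stopifnot(all(k >= 1), all(k == round(k)))
  if (params$epsilon == 0) return(rep(0, length(k)))
  if (mode == "simplified") {
    check_simplified_window(params, "scc_theory")
    if (is.null(cv2)) cv2 <- delta_v(1, params, "simplified")
    if (params$sigma_h == 0) return(rep(0, length(k)))
    return(Re(scc_beta(params) * exp(-theory_complex_coefs(params)$lam * k)) / cv2)
  }
  so2 <- params$sigma_ou^2; tau <- params$tau_ou
  harm <- if (params$sigma_h > 0)
    Re(scc_beta(params) * exp(-theory_complex_coefs(params)$lam * k))
  else rep(0, length(k))
  ou <- so2 * tau^2 * (1 - exp(-1 / tau))^2 * exp(-(k - 1) / tau)
  (harm + ou) / delta_v(1, params, "general")
}

#' Correlation lag of the ISI sequence (closed form)
#'
#' The correlation lag `tau_c = sum_{k>=1} |rho_k|` measures the temporal
#' extent of the serial correlations in units of the mean ISI. For the
#' damped-cosine closed form the infinite sum is evaluated exactly by
#' summing each run of constant sign as a geometric series (runs are
#' delimited by the zeros of the cosine), with a rigorous envelope bound on
#' the neglected tail (< 1e-12 in absolute value).
#'
#' `tau_c` grows with the quality factor (the decay per lag is
#' `exp(-pi*w/Q)`), has a pronounced maximum near `w = 1/2` (where the
#' oscillation alternates sign every lag with maximal amplitude, growing
#' without bound as Q increases), and nearly vanishes at integer `w`, where
#' the spike train is close to a renewal process.
#'
#' @param params A [pif_params()] object.
#' @param cv2 Optional squared CV for the prefactor; defaults to the
#'   simplified closed form.
#' @return A single non-negative number.
#' @export
correlation_lag_theory <- function(params, cv2 = NULL) {
  params <- as_pif_params(params)
  if (params$sigma_h == 0) return(0)
  check_simplified_window(params, "correlation_lag_theory")
  co <- scc_coefficients(params, cv2 = cv2)
  a <- co$amplitude; r <- co$decay; w1 <- co$omega1; phi <- co$phase
  if (r >= 1) stop("serial correlations do not decay (decay per lag >= 1): correlation lag diverges")
  z <- r * exp(1i * w1)
  # rho_k = a r^k cos(w1 k + phi); sign changes at w1 k + phi = pi/2 + m pi
  total <- 0
  k_lo <- 1
  tail_tol <- 1e-12
  m <- ceiling((w1 * 1 + phi - pi / 2) / pi)
  repeat {
    # largest integer lag strictly before the next zero of the cosine
    k_zero <- (pi / 2 + m * pi - phi) / w1
    while (k_zero <= k_lo) {
      m <- m + 1
      k_zero <- (pi / 2 + m * pi - phi) / w1
    }
    k_hi <- floor(k_zero)
    if (abs(cos(w1 * k_hi + phi)) < 1e-13) k_hi <- k_hi - 1 # lag exactly on a zero
    if (k_hi >= k_lo) {
      block <- a * Re(exp(1i * phi) * (z^k_lo - z^(k_hi + 1)) / (1 - z))
      total <- total + abs(block)
      k_lo <- k_hi + 1
    }
    m <- m + 1
    if (a * r^k_lo / (1 - r) < tail_tol) break
  }
  total
}

# Running integral of the total-noise autocorrelation, c(T) = int_0^T C_z,
# equal to DeltaV'(T)/2. Vectorized in T.
noise_corr_integral <- function(T, params, mode) {
  sh2 <- params$sigma_h^2; so2 <- params$sigma_ou^2
  tau <- params$tau_ou; g <- params$gamma; w1 <- params$omega1
  if (mode == "general") {
    cc <- theory_complex_coefs(params)
    harm <- if (sh2 > 0) Re(cc$alpha * (1 - exp(-cc$lam * T)) / cc$lam)
            else rep(0, length(T))
    ou <- so2 * tau * (1 - exp(-T / tau))
  } else {
    harm <- sh2 * (g + exp(-g * T / 2) *
                     (g / 2 * cos(w1 * T) + w1 * sin(w1 * T))) / w1^2
    ou <- so2 * tau
  }
  harm + ou
}

# Stationary autocorrelation C_z(T) of the total noise.
noise_autocorr <- function(T, params, mode) {
  sh2 <- params$sigma_h^2; so2 <- params$sigma_ou^2
  tau <- params$tau_ou; g <- params$gamma; w1 <- params$omega1
  harm <- if (mode == "general")
    sh2 * exp(-g * T / 2) * (cos(w1 * T) + g / (2 * w1) * sin(w1 * T))
  else
    sh2 * exp(-g * T / 2) * cos(w1 * T)
  ou <- if (mode == "general") so2 * exp(-T / tau) else rep(0, length(T))
  harm + ou
}

# Density abscissa grid: centered on the mean n, wide enough that the
# Gaussian tail mass is < 1e-6 even where DeltaV(T) oscillates.
density_grid <- function(n, params, mode, npoints) {
  sd_max <- sqrt(max(delta_v(seq(max(n - 1, 0.01), n + 1, length.out = 64),
                             params, mode)))
  lo <- max(1e-9, n - 10 * sd_max)
  hi <- n + 10 * sd_max
  seq(lo, hi, length.out = npoints)
}

#' Theoretical ISI density (and n-th-order interval density)
#'
#' Weak-noise first-passage density of the `n`-th threshold crossing of the
#' freely integrating voltage `x(T) = T + int_0^T z`, where `z = y + eta` is
#' the total stationary Gaussian noise. The density is the probability flux
#' through the threshold, evaluated exactly for the Gaussian system with the
#' spike-triggered (flux-biased) initial noise law:
#'
#' `p_n(T) = phi(a/s)/s * [1 + 2 c a / V + C - c^2/V + c^2 a^2 / V^2]`
#'
#' with `a = n - T`, `V = DeltaV(T)` the variance of the integrated noise,
#' `s = sqrt(V)`, `c = c(T)` the running integral of the noise
#' autocorrelation, and `C = C_z(T)` the noise autocorrelation itself.
#' Multiple threshold crossings are neglected (weak-noise assumption). The
#' prefactor can dip below zero where the harmonic modulation is strong;
#' negative values are clipped to zero and the curve renormalized, with a
#' warning reporting the clipped mass. For strong, coherent harmonic noise
#' the variance modulation carves dips at multiples of the drive period
#' `1/w`, and the density becomes multimodal.
#'
#' @param params A [pif_params()] object.
#' @param n Interval order (`n = 1` is the ISI density).
#' @param mode `"full"` (any Q, any tau_ou) or `"simplified"` (high-coherence
#'   short-OU reduction; requires `Q >= 5` and `tau_ou <= 0.2`, errors
#'   otherwise).
#' @param T_grid Optional abscissae (canonical time units). By default an
#'   adaptive grid spanning ten standard deviations around the mean.
#' @param npoints Number of grid points for the default grid.
#' @return A tibble with columns `time` and `density`, and attributes `mode`,
#'   `n` and `clipped_mass`.
#' @examples
#' p <- pif_params(w = 0.4, Q = 10, sigma_h = 0.05, sigma_ou = 0.02)
#' d <- isi_density(p)
#' sum(diff(d$time) * (head(d$density, -1) + tail(d$density, -1)) / 2)  # ~1
#' @export
isi_density <- function(params, n = 1, mode = c("full", "simplified"),
                        T_grid = NULL, npoints = 2001) {
  mode <- match.arg(mode)
  params <- as_pif_params(params)
  stopifnot(n >= 1, n == round(n))
  if (params$epsilon == 0)
    stop("zero noise: the ISI density is a point mass at the mean ISI")
  dv_mode <- if (mode == "simplified") "simplified" else "general"
  if (mode == "simplified") check_simplified_window(params, "isi_density")
  cv <- cv_theory(params, mode = "general")
  if (cv > 0.3)
    warning(sprintf("predicted CV = %.3g exceeds 0.3: outside the validated weak-noise regime", cv))
  if (is.null(T_grid)) T_grid <- density_grid(n, params, dv_mode, npoints)
  V <- delta_v(T_grid, params, dv_mode)
  s <- sqrt(pmax(V, 0))
  a <- n - T_grid
  cT <- noise_corr_integral(T_grid, params, dv_mode)
  Cz <- noise_autocorr(T_grid, params, dv_mode)
  ok <- s > 0 & T_grid > 0
  bracket <- rep(0, length(T_grid))
  bracket[ok] <- 1 + 2 * cT[ok] * a[ok] / V[ok] + Cz[ok] -
    cT[ok]^2 / V[ok] + cT[ok]^2 * a[ok]^2 / V[ok]^2
  dens <- rep(0, length(T_grid))
  dens[ok] <- stats::dnorm(a[ok] / s[ok]) / s[ok] * bracket[ok]
  raw_mass <- trapz(T_grid, dens)
  neg_mass <- -trapz(T_grid, pmin(dens, 0))
  if (neg_mass > 1e-12)
    warning(sprintf("clipped negative density mass %.3g (strong-noise artifact of the weak-noise form)",
                    neg_mass))
  dens <- pmax(dens, 0)
  norm <- trapz(T_grid, dens)
  if (!is.finite(norm) || norm <= 0) stop("degenerate density grid")
  out <- tibble::tibble(time = T_grid, density = dens / norm)
  attr(out, "mode") <- mode
  attr(out, "n") <- n
  attr(out, "raw_mass") <- raw_mass
  attr(out, "clipped_mass") <- neg_mass
  out
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Skewness of the theoretical ISI density
#'
#' Third standardized central moment of [isi_density()], computed by
#' quadrature on the density grid. For weak OU noise the sign alternates in
#' bands of the frequency ratio `w` (near-symmetric at `w = 1`); dominating
#' OU noise makes the density positively skewed for all `w`.
#'
#' @inheritParams isi_density
#' @return A single number.
#' @export
skewness_theory <- function(params, mode = c("full", "simplified"),
                            npoints = 4001) {
  mode <- match.arg(mode)
  params <- as_pif_params(params)
  d <- isi_density(params, n = 1, mode = mode, npoints = npoints)
  m1 <- trapz(d$time, d$time * d$density)
  m2 <- trapz(d$time, (d$time - m1)^2 * d$density)
  m3 <- trapz(d$time, (d$time - m1)^3 * d$density)
  m3 / m2^1.5
}

#' Population trend of a theoretical statistic
#'
#' Given a set of fitted parameter records (one per unit), evaluates a
#' theoretical statistic while sweeping one parameter (`Q` or `w`) over a
#' grid, holding each unit's other parameters fixed, and returns the
#' pointwise mean and SD across units. This is the model counterpart of
#' scatter plots of per-unit statistics versus oscillator parameters: the
#' mean curve is the sample-averaged tendency and the SD band its spread.
#'
#' @param params_df A data frame with one row per unit and columns `w`, `Q`,
#'   `sigma_h`, `sigma_ou` (optionally `tau_ou`).
#' @param vary Which parameter to sweep: `"Q"` or `"w"`.
#' @param grid Numeric grid of values for the swept parameter.
#' @param stat `"corrlag"` ([correlation_lag_theory()]) or `"skewness"`
#'   ([skewness_theory()]).
#' @return A tibble with columns `value` (grid), `mean`, `sd`, and attribute
#'   `curves` (units x grid matrix).
#' @export
population_trend <- function(params_df, vary = c("Q", "w"), grid,
                             stat = c("corrlag", "skewness")) {
  vary <- match.arg(vary)
  stat <- match.arg(stat)
  stopifnot(is.data.frame(params_df), nrow(params_df) >= 1, length(grid) >= 1)
  stat_fun <- switch(stat,
    corrlag = function(p) correlation_lag_theory(p),
    skewness = function(p) skewness_theory(p)
  )
  curves <- purrr::map(seq_len(nrow(params_df)), function(i) {
    row <- as.list(params_df[i, , drop = FALSE])
    purrr::map_dbl(grid, function(g) {
      row[[vary]] <- g
      stat_fun(as_pif_params(row))
    })
  })
  mat <- do.call(rbind, curves)
  out <- tibble::tibble(
    value = grid,
    mean = colMeans(mat),
    sd = if (nrow(mat) > 1) apply(mat, 2, stats::sd) else rep(0, ncol(mat))
  )
  attr(out, "curves") <- mat
  attr(out, "vary") <- vary
  attr(out, "stat") <- stat
  out
}
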
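# Non-parametric estimators for spike trains: ISI extraction, summary
# statistics, serial correlations with segment error bars, correlation lag,
# Welch power spectra and a stationarity filter.

# Accept a tibble from isis()/normalize_isis(), a data frame with an `isi`
# column, or a bare numeric vector.
isi_vector_of <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.data.frame(x)) {
    col <- if ("isi" %in% names(x)) x[["isi"]] else x[[1]]
    return(as.numeric(col))
  }
  stop("expected an ISI tibble, data frame, or numeric vector")
}

#' Interspike intervals of a spike train
#'
#' @param spike_times A [spike_train()], data frame with a `time` column, or
#'   numeric vector of strictly increasing spike times.
#' @return A tibble with columns `index` and `isi` (length one less than the
#'   number of spikes), in the input's time units.
#' @examples
#' isis(c(0, 1, 2, 3))
#' @export
isis <- function(spike_times) {
  t <- spike_times_of(spike_times)
  if (length(t) < 2) stop("need at least 2 spike times")
  bad <- which(diff(t) <= 0)
  if (length(bad) > 0)
    stop(sprintf("spike times not strictly increasing at index %d", bad[1] + 1))
  tibble::tibble(index = seq_len(length(t) - 1), isi = diff(t))
}

#' Summary statistics of an ISI sequence
#'
#' Mean, coefficient of variation (SD over mean) and skewness (third
#' standardized central moment, moment estimator) of the intervals.
#'
#' @param isis ISI sequence (tibble from [isis()] or numeric vector).
#' @return A one-row tibble with columns `n`, `mean`, `sd`, `cv`, `skewness`.
#' @export
summary_stats <- function(isis) {
  x <- isi_vector_of(isis)
  n <- length(x)
  if (n < 3) stop("need at least 3 intervals (skewness requires 3)")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  tibble::tibble(n = n, mean = m, sd = sqrt(m2), cv = sqrt(m2) / m,
                 skewness = if (m2 > 0) m3 / m2^1.5 else 0)
}

scc_of_vector <- function(x, kmax) {
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= 0) stop("constant ISI sequence: serial correlations are undefined")
  vapply(seq_len(kmax), function(k) {
    (mean(x[1:(n - k)] * x[(1 + k):n]) - m^2) / v
  }, numeric(1))
}

#' Serial correlation coefficients of an ISI sequence
#'
#' Estimates `rho_k = (<I_i I_{i+k}> - <I>^2) / var(I)` for lags
#' `k = 1..kmax`, using the pooled full-sequence mean and variance (the
#' stationary form of the estimator). For a renewal (independent-interval)
#' sequence the estimator has bias of order `-1/n`, which is not corrected.
#'
#' @param isis ISI sequence (tibble or numeric vector).
#' @param kmax Largest lag.
#' @return A tibble with columns `lag` and `rho`.
#' @export
scc_estimate <- function(isis, kmax = 100) {
  x <- isi_vector_of(isis)
  stopifnot(kmax >= 1)
  if (length(x) <= kmax + 1) stop("ISI sequence shorter than kmax + 2")
  if (length(x) < 10 * kmax)
    warning("fewer than 10*kmax intervals: serial correlation estimates will be noisy")
  tibble::tibble(lag = seq_len(kmax), rho = scc_of_vector(x, kmax))
}

#' Serial correlations with segment-based error bars
#'
#' Splits the ISI sequence into `n_segments` consecutive segments of
#' `segment_len` intervals, estimates the serial correlations in each, and
#' reports the across-segment SD as the per-lag error bar, alongside the
#' pooled estimate from the full sequence. This mirrors the treatment of
#' long experimental records, where segmenting exposes the variability due
#' to residual slow nonstationarity.
#'
#' @inheritParams scc_estimate
#' @param n_segments Number of segments (reduced with a warning if the
#'   sequence is too short).
#' @param segment_len Intervals per segment.
#' @return A tibble with columns `lag`, `rho` (pooled), `se`; attributes
#'   `n_segments` and `segment_len`.
#' @export
scc_errorbars <- function(isis, kmax = 100, n_segments = 20,
                          segment_len = 2000) {
  x <- isi_vector_of(isis)
  n <- length(x)
  n_segments <- as.integer(n_segments)
  if (n < n_segments * segment_len) {
    n_segments <- as.integer(floor(n / segment_len))
    warning(sprintf("sequence shorter than n_segments*segment_len; using %d segments",
                    n_segments))
  }
  pooled <- scc_estimate(x, kmax)
  if (n_segments >= 2) {
    seg_rho <- vapply(seq_len(n_segments), function(i) {
      seg <- x[((i - 1) * segment_len + 1):(i * segment_len)]
      scc_of_vector(seg, kmax)
    }, numeric(kmax))
    se <- apply(seg_rho, 1, stats::sd)
  } else {
    warning("fewer than 2 usable segments: no error bars")
    se <- rep(NA_real_, kmax)
  }
  out <- tibble::tibble(lag = pooled$lag, rho = pooled$rho, se = se)
  attr(out, "n_segments") <- n_segments
  attr(out, "segment_len") <- segment_len
  out
}

#' Correlation lag of a measured SCC series
#'
#' Sums `|rho_k|` from lag 1 up to a truncation lag. Under estimator noise
#' the untruncated sum grows without bound, so by default (`rule =
#' "noise_floor"`) the sum stops at the first run of 3 consecutive lags with
#' `|rho_k| < 2 se_k`, capped at lag `kmax_cap`; `rule = "none"` sums all
#' provided lags.
#'
#' @param scc A tibble with columns `lag`, `rho` and (for the noise-floor
#'   rule) `se`, as returned by [scc_errorbars()].
#' @param rule Truncation rule: `"noise_floor"` or `"none"`.
#' @param kmax_cap Hard cap on the truncation lag.
#' @return A one-row tibble with columns `tau_c`, `k_trunc`, `rule`.
#' @export
correlation_lag_estimate <- function(scc, rule = c("noise_floor", "none"),
                                     kmax_cap = 200) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(scc), all(c("lag", "rho") %in% names(scc)))
  ord <- order(scc$lag)
  lag <- scc$lag[ord]; rho <- scc$rho[ord]
  if (rule == "noise_floor") {
    if (!("se" %in% names(scc)) || all(is.na(scc$se)))
      stop("noise-floor truncation requires per-lag standard errors (`se`)")
    se <- scc$se[ord]
    below <- abs(rho) < 2 * se
    k_trunc <- length(lag)
    run <- 0
    for (i in seq_along(lag)) {
      run <- if (isTRUE(below[i])) run + 1 else 0
      if (run >= 3) { k_trunc <- i - 3; break }
    }
    k_trunc <- min(k_trunc, kmax_cap)
  } else {
    k_trunc <- min(length(lag), kmax_cap)
  }
  tau_c <- if (k_trunc >= 1) sum(abs(rho[seq_len(k_trunc)])) else 0
  tibble::tibble(tau_c = tau_c, k_trunc = k_trunc, rule = rule)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

#' Welch power spectral density of a spike train
#'
#' The spike train is represented as a sum of rectangular pulses of width
#' `delta` and height `1/delta` (one per spike), with the mean firing rate
#' subtracted, and the PSD is estimated by Welch's method: the binned signal
#' is split into overlapping windowed segments whose periodograms are
#' averaged. The normalization is such that a Poisson train of rate `r` has
#' a flat spectrum at level `r`. For a neuron driven by a stochastic
#' oscillation the PSD shows peaks at the drive frequency `f_e = w * r0` and
#' at the firing rate `f_a = r0`, plus sidebands.
#'
#' @param spike_times Spike train; times in seconds (a canonical-unit
#'   [spike_train()] with `rate_hz` set is converted automatically).
#' @param delta Sampling interval of the binned train, seconds.
#' @param nfft Welch segment length in samples.
#' @param overlap Fractional segment overlap.
#' @param window Taper: `"hann"` or `"rect"`.
#' @return A tibble with columns `freq` (Hz) and `power`; attributes `rate`,
#'   `duration`, `delta` and `welch` (segment configuration).
#' @export
psd_estimate <- function(spike_times, delta = 0.001, nfft = 2^14,
                         overlap = 0.5, window = c("hann", "rect")) {
  window <- match.arg(window)
  t <- spike_times_of(spike_times)
  if (is.data.frame(spike_times) &&
      identical(attr(spike_times, "units"), "canonical")) {
    p <- attr(spike_times, "params")
    if (!is.null(p) && !is.null(p$rate_hz)) t <- t / p$rate_hz
  }
  if (length(t) < 2) stop("need at least 2 spikes")
  t <- t - t[1]
  duration <- t[length(t)]
  nbins <- floor(duration / delta)
  if (nbins < 1.5 * nfft)
    stop("record too short for the requested Welch segment length (need >= 2 overlapping segments)")
  counts <- tabulate(pmin(floor(t / delta) + 1, nbins), nbins)
  x <- counts / delta
  x <- x - mean(x)
  win <- if (window == "hann") hann_window(nfft) else rep(1, nfft)
  hop <- max(1, floor(nfft * (1 - overlap)))
  starts <- seq(1, nbins - nfft + 1, by = hop)
  acc <- numeric(nfft %/% 2 + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nfft - 1)] * win
    X <- stats::fft(seg)
    P <- (Mod(X)^2) * delta / sum(win^2)
    acc <- acc + P[seq_len(nfft %/% 2 + 1)]
  }
  power <- acc / length(starts)
  freq <- (seq_len(nfft %/% 2 + 1) - 1) / (nfft * delta)
  out <- tibble::tibble(freq = freq, power = power)
  attr(out, "rate") <- (length(t) - 1) / duration
  attr(out, "duration") <- duration
  attr(out, "delta") <- delta
  attr(out, "welch") <- list(nfft = nfft, overlap = overlap, window = window,
                             n_segments = length(starts))
  out
}

#' Longest stationary stretch of a spike train
#'
#' Computes a moving-average firing rate over windows of length `window`
#' seconds and returns the longest contiguous stretch in which every
#' windowed rate stays within `+/- tol` of the stretch's own mean rate.
#' Recordings with rate drift or steps are cut at the offending boundary.
#'
#' @param spike_times Spike train with times in seconds (or any consistent
#'   unit; `window` is in the same unit).
#' @param window Moving-average window length (default 10 s).
#' @param tol Allowed fractional deviation of the windowed rate (default 2%).
#' @param hop Spacing of window positions (default `window/10`).
#' @return A [spike_train()] restricted to the admissible stretch, with
#'   attributes `rejected_fraction`, `t_start`, `t_end`. If no stretch of at
#'   least one window is admissible the result has zero rows and attribute
#'   `admissible = FALSE` (with a warning).
#' @export
stationarity_filter <- function(spike_times, window = 10, tol = 0.02,
                                hop = window / 10) {
  t <- spike_times_of(spike_times)
  if (length(t) < 2) stop("need at least 2 spikes")
  units <- if (is.data.frame(spike_times) && !is.null(attr(spike_times, "units")))
    attr(spike_times, "units") else "seconds"
  duration <- t[length(t)] - t[1]
  if (duration <= window)
    stop("record shorter than the stationarity window")
  if (!is.finite(tol)) {
    out <- spike_train(t, units = units, params = attr(spike_times, "params"))
    attr(out, "rejected_fraction") <- 0
    attr(out, "t_start") <- t[1]; attr(out, "t_end") <- t[length(t)]
    attr(out, "admissible") <- TRUE
    return(out)
  }
  centers <- seq(t[1] + window / 2, t[length(t)] - window / 2, by = hop)
  lo <- findInterval(centers - window / 2, t)
  hi <- findInterval(centers + window / 2, t)
  rates <- (hi - lo) / window
  nw <- length(rates)
  # longest run [i, j] of windows with all rates within tol of the run mean
  best <- c(0L, 0L); best_len <- 0
  i <- 1L
  csum <- cumsum(rates)
  for (i in seq_len(nw)) {
    if (nw - i + 1 <= best_len) break
    rmax <- -Inf; rmin <- Inf
    for (j in i:nw) {
      rmax <- max(rmax, rates[j]); rmin <- min(rmin, rates[j])
      mu <- (csum[j] - if (i > 1) csum[i - 1] else 0) / (j - i + 1)
      if (rmax > (1 + tol) * mu || rmin < (1 - tol) * mu) break
      if (j - i + 1 > best_len) { best <- c(i, j); best_len <- j - i + 1 }
    }
  }
  if (best_len == 0) {
    warning("no admissible stationary stretch found")
    out <- spike_train(numeric(0), units = units)
    attr(out, "rejected_fraction") <- 1
    attr(out, "admissible") <- FALSE
    return(out)
  }
  t_start <- centers[best[1]] - window / 2
  t_end <- centers[best[2]] + window / 2
  keep <- t[t >= t_start & t <= t_end]
  out <- spike_train(keep, units = units, params = attr(spike_times, "params"))
  attr(out, "rejected_fraction") <- 1 - length(keep) / length(t)
  attr(out, "t_start") <- t_start; attr(out, "t_end") <- t_end
  attr(out, "admissible") <- TRUE
  out
}
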
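test_that("ISI extraction validates monotonicity and differences", {
  expect_equal(isis(c(0, 1, 2, 3))$isi, c(1, 1, 1))
  expect_error(isis(c(0, 0.5, 0.4)), "index 3")
  expect_error(isis(1), "at least 2")
  st <- simulate_pif(pif_params(0.5, 10, 0, 0), 50, seed = 1)
  expect_lt(diff(range(isis(st)$isi)), 1e-9)
})

test_that("summary statistics handle degenerate and symmetric cases", {
  s <- summary_stats(rep(1.3, 10))
  expect_equal(s$cv, 0); expect_equal(s$skewness, 0)
  s2 <- summary_stats(rep(c(0.9, 1.1), 25))
  expect_equal(s2$skewness, 0, tolerance = 1e-12)
  expect_equal(s2$mean, 1)
  expect_error(summary_stats(c(1, 2)), "at least 3")
})

test_that("serial-correlation estimator: exact alternation and renewal null", {
  # deterministic alternation: rho_1 = -1 exactly under the pooled estimator
  alt <- rep(c(1, 2), 500)
  expect_equal(scc_estimate(alt, kmax = 2)$rho[1], -1, tolerance = 1e-9)
  expect_error(scc_estimate(rep(1, 100), kmax = 3), "constant")
  # i.i.d. null: 95% of lags inside 3/sqrt(n)
  set.seed(5)
  x <- rgamma(20000, shape = 25, rate = 25)
  r <- scc_estimate(x, kmax = 60)$rho
  expect_gt(mean(abs(r) < 3 / sqrt(length(x))), 0.95)
  expect_warning(scc_estimate(rnorm(150, 10), kmax = 40), "noisy")
})

test_that("segment error bars have renewal-theory magnitude", {
  set.seed(8)
  x <- rgamma(40000, 25, 25)
  sc <- scc_errorbars(x, kmax = 20, n_segments = 20, segment_len = 2000)
  expect_identical(attr(sc, "n_segments"), 20L)
  # per-segment SD of an SCC estimate over 2000 iid intervals ~ 1/sqrt(2000)
  expect_lt(abs(mean(sc$se) - 1 / sqrt(2000)) / (1 / sqrt(2000)), 0.25)
  # duplicated identical segments carry no spread
  seg <- rgamma(2000, 25, 25)
  sc0 <- suppressWarnings(scc_errorbars(rep(seg, 4), kmax = 5,
                                        n_segments = 4, segment_len = 2000))
  expect_equal(sc0$se, rep(0, 5), tolerance = 1e-12)
})

test_that("correlation-lag estimate truncates at the noise floor", {
  sc <- tibble::tibble(lag = 1:50, rho = rep(0, 50), se = rep(0.01, 50))
  est <- correlation_lag_estimate(sc)
  expect_equal(est$tau_c, 0)
  # exact theoretical series, no truncation: matches the closed form
  p <- pif_params(0.45, 20, 0.2, 0.1)
  k <- 1:5000
  sc2 <- tibble::tibble(lag = k, rho = scc_theory(k, p, mode = "simplified"))
  est2 <- correlation_lag_estimate(sc2, rule = "none", kmax_cap = 5000)
  expect_equal(est2$tau_c, correlation_lag_theory(p), tolerance = 1e-4)
  expect_error(correlation_lag_estimate(sc2, rule = "noise_floor"), "se")
})

test_that("Welch PSD: periodic peak, flat Poisson level, drive peak", {
  # strictly periodic train at 50 Hz: dominant peak at the firing rate
  st <- seq(0, 200, by = 0.02)
  psd <- psd_estimate(st)
  low <- psd[psd$freq > 10 & psd$freq < 75, ]
  pk <- low$freq[which.max(low$power)]
  expect_equal(pk, 50, tolerance = 0.01)
  # Poisson surrogate: flat spectrum at the rate level (within 10%)
  set.seed(9)
  tp <- cumsum(rexp(30000, rate = 60))
  psd_p <- psd_estimate(tp)
  lvl <- mean(psd_p$power[psd_p$freq > 5])
  expect_lt(abs(lvl - attr(psd_p, "rate")) / attr(psd_p, "rate"), 0.1)
  expect_error(psd_estimate(seq(0, 5, by = 0.02)), "Welch segment")
  # simulated drive leaves a spectral peak near w * r0
  p <- pif_params(0.5, 20, 0.2, 0.05, rate_hz = 50)
  stw <- simulate_pif(p, 2e4, seed = 12)
  psd_w <- psd_estimate(stw)
  band <- psd_w[psd_w$freq > 12.5 & psd_w$freq < 40, ]
  expect_equal(band$freq[which.max(band$power)], 25, tolerance = 0.06)
})

test_that("stationarity filter keeps homogeneous trains and cuts rate steps", {
  p <- pif_params(0.5, 15, 0.1, 0.1, rate_hz = 50)
  st <- simulate_pif(p, 15000, seed = 13)
  kept <- stationarity_filter(st)
  expect_lt(attr(kept, "rejected_fraction"), 0.15)
  expect_true(attr(kept, "admissible"))
  # infinite tolerance keeps everything
  all_kept <- stationarity_filter(st, tol = Inf)
  expect_equal(nrow(all_kept), nrow(st))
  # 10% rate step mid-recording: the filter must cut near the step
  t1 <- seq(0, 150, by = 0.02)
  t2 <- seq(150.018, 280, by = 0.018)
  step_train <- c(t1, t2)
  res <- stationarity_filter(step_train, window = 10, tol = 0.02)
  expect_true(attr(res, "t_start") > 140 || attr(res, "t_end") < 160)
  expect_gt(attr(res, "rejected_fraction"), 0.3)
})
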
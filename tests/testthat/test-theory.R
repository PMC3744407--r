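test_that("closed-form CV: limits, additivity, and minima at integer w", {
  expect_equal(cv_theory(pif_params(0.7, 10, 0, 0)), 0)
  # perturbative structure: harmonic and OU contributions add in CV^2
  p_both <- pif_params(0.62, 14, 0.13, 0.21, tau_ou = 0.15)
  p_h <- pif_params(0.62, 14, 0.13, 0, tau_ou = 0.15)
  p_o <- pif_params(0.62, 14, 0, 0.21, tau_ou = 0.15)
  for (m in c("general", "simplified"))
    expect_equal(cv_theory(p_both, m)^2,
                 cv_theory(p_h, m)^2 + cv_theory(p_o, m)^2, tolerance = 1e-12)
  # driving at a multiple of the firing rate lets the neuron fire regularly
  ws <- seq(0.8, 2.2, by = 0.05)
  cvs <- sapply(ws, function(w) cv_theory(pif_params(w, 50, 0.2, 0)))
  for (wi in c(1, 2)) {
    i <- which(ws == wi)
    expect_lt(cvs[i], cvs[i - 1])
    expect_lt(cvs[i], cvs[i + 1])
  }
  # overall decline in w
  expect_lt(cv_theory(pif_params(2.05, 50, 0.2, 0)),
            cv_theory(pif_params(0.55, 50, 0.2, 0)))
  expect_warning(cv_theory(pif_params(0.5, 2, 0.1, 0.1), "simplified"),
                 "validity")
})

test_that("ISI density normalizes, respects its validity window, and matches simulation", {
  p <- shared_sim()$params
  d <- isi_density(p, mode = "full", npoints = 4001)
  expect_true(all(d$density >= 0))
  expect_equal(trapz_num(d$time, d$density), 1, tolerance = 1e-6)
  # simplified mode agrees with the full form deep in the high-Q short-OU regime
  p2 <- pif_params(0.6, 25, 0.15, 0.1, tau_ou = 0.05)
  d1 <- isi_density(p2, mode = "full")
  d2 <- isi_density(p2, mode = "simplified", T_grid = d1$time)
  expect_lt(max(abs(d1$density - d2$density)) / max(d1$density), 0.01)
  # validity guards
  expect_error(isi_density(pif_params(0.5, 2, 0.1, 0.1), mode = "simplified"),
               "Q >= 5")
  expect_error(isi_density(pif_params(0.5, 10, 0, 0)), "zero noise")
  expect_warning(isi_density(pif_params(0.5, 10, 0.1, 0.9, tau_ou = 0.5)),
                 "0.3")
  # Kolmogorov distance against the empirical CDF of 1e5 simulated ISIs
  s <- shared_sim()
  dfull <- isi_density(s$params, mode = "full", npoints = 4001)
  cdf <- cumsum(c(0, diff(dfull$time) *
                    (head(dfull$density, -1) + tail(dfull$density, -1)) / 2))
  ks <- max(abs(stats::ecdf(s$isi)(dfull$time) - cdf))
  expect_lt(ks, 0.01)
})

test_that("density narrows onto the mean ISI as the noise vanishes", {
  sds <- sapply(c(0.05, 0.02, 0.005), function(s) {
    d <- isi_density(pif_params(0.5, 20, s, s / 2))
    m <- trapz_num(d$time, d$time * d$density)
    sqrt(trapz_num(d$time, (d$time - m)^2 * d$density))
  })
  expect_true(all(diff(sds) < 0))
  d <- isi_density(pif_params(0.5, 20, 0.005, 0.0025))
  expect_equal(trapz_num(d$time, d$time * d$density), 1, tolerance = 1e-3)
})

test_that("skewness alternates sign in frequency-ratio bands", {
  # dominating broadband (exponentially correlated) noise: positive skew
  expect_gt(skewness_theory(pif_params(0.5, 10, 0, 0.2)), 0)
  # near-symmetric density when the drive matches the firing rate
  expect_lt(abs(skewness_theory(pif_params(1, 50, 0.15, 0.02))), 0.05)
  # sign bands on either side
  expect_gt(skewness_theory(pif_params(0.4, 30, 0.15, 0.02)), 0)
  expect_lt(skewness_theory(pif_params(0.75, 30, 0.15, 0.02)), 0)
  # symmetric limit
  expect_lt(abs(skewness_theory(pif_params(1, 50, 0.01, 0.005))), 0.05)
})

test_that("n-th order variance: definitional n=1 and renewal linearity", {
  p <- pif_params(0.55, 18, 0.2, 0.12)
  expect_equal(nth_order_variance(1, p), cv_theory(p)^2, tolerance = 1e-14)
  # white-noise-like PIF: variance linear in n
  pr <- pif_params(0.5, 10, 0, 0.2, tau_ou = 0.01)
  v <- nth_order_variance(c(1, 5, 20), pr)
  expect_equal(v[2] / v[1], 5, tolerance = 0.01)
  expect_equal(v[3] / v[1], 20, tolerance = 0.01)
})

test_that("serial correlations: bounds, renewal limits, damped-cosine coefficients", {
  p <- pif_params(0.408, 16.4, 0.197, 0.226)
  for (m in c("general", "simplified"))
    expect_true(all(abs(scc_theory(1:200, p, mode = m)) <= 1))
  # renewal: no harmonic noise, short OU
  expect_true(all(abs(scc_theory(1:20, pif_params(0.5, 10, 0, 0.2,
                                                  tau_ou = 0.001))) < 1e-3))
  expect_equal(scc_theory(1:5, pif_params(0.5, 10, 0, 0)), rep(0, 5))
  # drive at the firing rate: near-renewal spiking
  expect_true(all(abs(scc_theory(1:50, pif_params(1, 25, 0.2, 0.05))) < 0.02))
  # coefficients reproduce the sampled damped oscillation
  co <- scc_coefficients(p)
  expect_gt(co$decay, 0); expect_lt(co$decay, 1)
  expect_equal(co$decay, exp(-pi * p$w / p$Q), tolerance = 1e-12)
  k <- 1:40
  expect_equal(scc_theory(k, p, mode = "simplified"),
               co$amplitude * co$decay^k * cos(co$omega1 * k + co$phase),
               tolerance = 1e-10)
})

test_that("correlation lag: renewal zero, growth in Q, resonance at w = 1/2", {
  expect_equal(correlation_lag_theory(pif_params(0.5, 20, 0, 0.1)), 0)
  tcq <- sapply(c(5, 10, 20, 40),
                function(Q) correlation_lag_theory(pif_params(0.45, Q, 0.2, 0.1)))
  expect_true(all(diff(tcq) > 0))
  tc <- sapply(c(0.45, 0.5, 0.55),
               function(w) correlation_lag_theory(pif_params(w, 25, 0.2, 0.1)))
  expect_gt(tc[2], tc[1]); expect_gt(tc[2], tc[3])
})

test_that("population trend machinery averages correctly", {
  one <- data.frame(w = 0.45, Q = 15, sigma_h = 0.2, sigma_ou = 0.15)
  tr1 <- population_trend(one, vary = "Q", grid = c(8, 16, 24), stat = "corrlag")
  expect_equal(tr1$sd, rep(0, 3))
  two <- rbind(one, one)
  tr2 <- population_trend(two, vary = "Q", grid = c(8, 16, 24), stat = "corrlag")
  expect_equal(tr2$mean, tr1$mean, tolerance = 1e-12)
  expect_equal(tr2$sd, rep(0, 3))
  expect_error(population_trend(one[0, ], vary = "Q", grid = 1:3))
})
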
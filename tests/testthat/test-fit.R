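test_that("ISI normalization is exact and reversible", {
  expect_equal(normalize_isis(c(2, 2, 2))$isi, c(1, 1, 1))
  expect_equal(attr(normalize_isis(c(2, 2, 2)), "scale"), 2)
  set.seed(3)
  x <- rgamma(500, 20, 18)
  nz <- normalize_isis(x)
  expect_equal(mean(nz$isi), 1, tolerance = 1e-15)
  expect_equal(nz$isi * attr(nz, "scale"), x, tolerance = 1e-15)
})

test_that("initial frequency ratio comes from the two spectral peaks", {
  f <- seq(0.5, 120, by = 0.5)
  pow <- 1 + 30 * dnorm(f, 26, 1.5) + 40 * dnorm(f, 53, 2)
  psd <- tibble::tibble(freq = f, power = pow)
  wi <- initial_w_from_psd(psd, rate_hz = 53)
  expect_equal(wi$w_init, 26 / 53, tolerance = 1e-6)
  expect_false(wi$fallback)
  # flat spectrum: no peaks, fall back to mid-range
  flat <- tibble::tibble(freq = f, power = rep(1, length(f)))
  expect_warning(wf <- initial_w_from_psd(flat, rate_hz = 53), "fall")
  expect_equal(wf$w_init, 0.5)
  # end-to-end: simulated train, peak ratio near the true w
  p <- pif_params(0.45, 20, 0.2, 0.1, rate_hz = 50)
  st <- simulate_pif(p, 2e4, seed = 31)
  wi2 <- initial_w_from_psd(psd_estimate(st))
  expect_lt(abs(wi2$w_init - 0.45), 0.02)
})

test_that("noiseless SCC fit recovers the generating parameters (inverse crime)", {
  cv <- 0.181
  k <- 1:80
  rho <- oscspike:::scc_model(k, 16.40, 0.408, 0.197, cv^2)
  fit <- fit_scc(tibble::tibble(lag = k, rho = rho), cv_measured = cv,
                 w_init = 0.41)
  expect_true(fit$converged)
  expect_equal(fit$Q, 16.40, tolerance = 1e-5)
  expect_equal(fit$w, 0.408, tolerance = 1e-6)
  expect_equal(fit$sigma_h, 0.197, tolerance = 1e-5)
  expect_false(fit$unidentifiable)
})

test_that("an SCC at the noise floor is flagged unidentifiable", {
  sc <- tibble::tibble(lag = 1:60, rho = rep(0, 60), se = rep(0.02, 60))
  attr(sc, "n_segments") <- 20
  fit <- fit_scc(sc, cv_measured = 0.15, w_init = 0.5)
  expect_true(fit$unidentifiable)
  expect_lt(fit$sigma_h, 0.02)
})

test_that("CV inversion for the OU intensity is exact and flags infeasibility", {
  # no harmonic noise: D = cv^2 / 2
  expect_equal(d_ou_from_cv(0.2, 10, 0.5, 0)$d_ou, 0.02, tolerance = 1e-12)
  # reference afferent 2 row reproduces the printed intensity
  d2 <- d_ou_from_cv(0.153, 22.38, 0.495, 0.198)
  expect_true(d2$feasible)
  expect_equal(d2$d_ou, 3.20e-3, tolerance = 0.05)
  # definitional round trip through the closed-form CV
  d <- d_ou_from_cv(0.18, 16, 0.42, 0.15)$d_ou
  p <- pif_params(0.42, 16, 0.15, sigma_ou = sqrt(d / 0.1), tau_ou = 0.1)
  expect_equal(cv_theory(p, mode = "simplified"), 0.18, tolerance = 1e-12)
  # harmonic contribution exceeding the measured CV^2 is infeasible
  inf <- d_ou_from_cv(0.05, 16, 0.42, 0.3)
  expect_false(inf$feasible)
  expect_equal(inf$d_ou, 0)
})

test_that("full extraction pipeline is deterministic and accurate on a surrogate", {
  p <- table1_params(2)$params
  st <- simulate_pif(p, 2.2e4, seed = 77)
  expect_warning(f1 <- extract_parameters(st), "segments|4000")
  f2 <- suppressWarnings(extract_parameters(st))
  expect_identical(tidy(f1)$estimate, tidy(f2)$estimate)
  expect_lt(abs(f1$w - 0.495), 0.02)
  expect_lt(abs(f1$sigma_h - 0.198) / 0.198, 0.25)
  expect_true(f1$converged)
  # tidy/glance interfaces
  td <- tidy(f1)
  expect_identical(td$term, c("Q", "w", "sigma_h", "d_ou", "sigma_ou"))
  expect_true(all(c("cv", "rate_hz", "converged") %in% names(glance(f1))))
  # short records warn about imprecision
  st_short <- simulate_pif(p, 3000, seed = 78)
  w <- capture_warnings(extract_parameters(st_short))
  expect_true(any(grepl("4000", w)))
})
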
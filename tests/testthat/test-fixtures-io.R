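test_that("reference afferent parameter sets carry the printed values", {
  t1 <- table1_params(1)
  expect_equal(t1$rate_hz, 53.00)
  expect_equal(t1$cv, 0.181)
  expect_equal(t1$params$w, 0.408)
  expect_equal(t1$params$Q, 16.40)
  expect_equal(t1$params$sigma_h, 0.197)
  expect_equal(t1$d_ou, 5.10e-3)
  expect_equal(t1$params$sigma_ou, sqrt(5.10e-3 / 0.1), tolerance = 1e-12)
  t3 <- table1_params(3)
  expect_equal(c(t3$rate_hz, t3$cv, t3$params$w, t3$params$Q, t3$params$sigma_h,
                 t3$d_ou),
               c(38.29, 0.164, 0.591, 19.38, 0.224, 6.10e-3))
  expect_error(table1_params(4), "unknown")
})

test_that("population sampling stays inside the published ranges", {
  rg <- population_ranges()
  pop <- sample_population(56, seed = 7)
  expect_identical(nrow(pop), 56L)
  for (nm in c("rate_hz", "w", "Q", "sigma_h", "sigma_ou", "n_isis")) {
    i <- match(nm, rg$param)
    expect_true(all(pop[[nm]] >= rg$lower[i] & pop[[nm]] <= rg$upper[i]))
  }
  expect_identical(sample_population(56, seed = 7), pop)
  # empirical extremes approach the bounds in a large sample
  big <- sample_population(1000, seed = 8)
  i <- match("w", rg$param)
  expect_lt(big$w[which.min(big$w)] - rg$lower[i], 0.01)
  expect_lt(rg$upper[i] - max(big$w), 0.01)
})

test_that("surrogate datasets are reproducible and round-trip through files", {
  dir <- withr::local_tempdir()
  pars <- tibble::tibble(unit = 1:2, w = c(0.45, 0.5), Q = c(15, 20),
                         sigma_h = c(0, 0.2), sigma_ou = c(0, 0.1),
                         tau_ou = 0.1, rate_hz = c(50, 40))
  man <- surrogate_dataset(pars, n_isis = 1500, seed = 5, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # zero-noise unit: equally spaced spike times at 1/50 s
  st1 <- read_spike_times(file.path(dir, man$file[1]))
  expect_lt(diff(range(diff(st1$time))), 1e-9)
  expect_equal(mean(diff(st1$time)), 1 / 50, tolerance = 1e-9)
  expect_equal(attr(st1, "rate_hz"), 50)
  # noisy unit: mean rate near the requested rate
  st2 <- read_spike_times(file.path(dir, man$file[2]))
  expect_lt(abs(1 / mean(diff(st2$time)) - 40) / 40, 0.03)
  # manifest records the ground truth for recovery scoring
  m <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_equal(m$w, pars$w)
  expect_equal(m$seed, c(6, 7))
  # regenerating with the same seed reproduces the files bit-for-bit
  dir2 <- withr::local_tempdir()
  surrogate_dataset(pars, n_isis = 1500, seed = 5, out_dir = dir2)
  expect_identical(readLines(file.path(dir, man$file[2])),
                   readLines(file.path(dir2, man$file[2])))
})

test_that("spike-time files and parameter configs round-trip", {
  dir <- withr::local_tempdir()
  p <- pif_params(0.47, 18, 0.21, 0.14, tau_ou = 0.2, rate_hz = 44)
  st <- simulate_pif(p, 500, seed = 9)
  f <- file.path(dir, "spikes.txt")
  write_spike_times(st, f)
  back <- read_spike_times(f)
  expect_equal(back$time, st$time, tolerance = 1e-12)
  expect_equal(attr(back, "rate_hz"), 44)
  for (ext in c("cfg.yaml", "cfg.json")) {
    cf <- file.path(dir, ext)
    write_pif_config(p, cf)
    q <- read_pif_config(cf)
    expect_equal(q[c("w", "Q", "sigma_h", "sigma_ou", "tau_ou", "rate_hz")],
                 p[c("w", "Q", "sigma_h", "sigma_ou", "tau_ou", "rate_hz")])
  }
})

test_that("surrogate population reproduces the correlation-lag trends", {
  pop <- sample_population(56, seed = 21)
  tr <- population_trend(pop[1:12, ], vary = "Q", grid = c(5, 12, 20, 30),
                         stat = "corrlag")
  expect_true(all(diff(tr$mean) > 0))
  expect_true(all(tr$sd[-1] > 0))
  # per-unit tau_c rises with the unit's coherence, peaks for w near 1/2
  tau <- purrr::map_dbl(seq_len(nrow(pop)), function(i)
    correlation_lag_theory(pif_params(pop$w[i], pop$Q[i], pop$sigma_h[i],
                                      pop$sigma_ou[i])))
  expect_gt(cor(pop$Q, tau, method = "spearman"), 0.5)
  expect_lt(abs(pop$w[which.max(tau)] - 0.5), 0.05)
})
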
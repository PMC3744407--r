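# Surrogate data emulating a sample of paddlefish electroreceptor afferents:
# golden parameter sets for three reference units and uniform sampling within
# the published population ranges, so that every pipeline stage is testable
# without recordings.

table1_data <- function() {
  tibble::tibble(
    afferent = 1:3,
    rate_hz = c(53.00, 49.42, 38.29),
    cv = c(0.181, 0.153, 0.164),
    w = c(0.408, 0.495, 0.591),
    Q = c(16.40, 22.38, 19.38),
    sigma_h = c(0.197, 0.198, 0.224),
    d_ou = c(5.10e-3, 3.20e-3, 6.10e-3)
  )
}

#' Reference parameter sets of three fitted afferents
#'
#' Returns the fitted model parameters of one of three reference
#' electroreceptor afferents (mean firing rate, measured CV, frequency ratio
#' `w`, quality factor `Q`, harmonic-noise SD `sigma_h`, OU intensity
#' `D_ou`), as a ready-to-simulate [pif_params()] plus the measured
#' quantities. The OU SD is implied by the intensity through the default
#' correlation time: `sigma_ou = sqrt(d_ou / tau_ou)`.
#'
#' @param afferent_id 1, 2 or 3.
#' @param tau_ou OU correlation time used for the intensity-to-SD
#'   conversion (default 0.1 mean ISIs).
#' @return A list with elements `params` ([pif_params()]), `cv` (measured),
#'   `rate_hz`, `d_ou`.
#' @examples
#' table1_params(1)$params
#' @export
table1_params <- function(afferent_id, tau_ou = 0.1) {
  tab <- table1_data()
  if (!afferent_id %in% tab$afferent)
    stop("unknown afferent id; use 1, 2 or 3")
  row <- tab[tab$afferent == afferent_id, ]
  list(
    params = pif_params(
      w = row$w, Q = row$Q, sigma_h = row$sigma_h,
      sigma_ou = sqrt(row$d_ou / tau_ou), tau_ou = tau_ou,
      rate_hz = row$rate_hz
    ),
    cv = row$cv, rate_hz = row$rate_hz, d_ou = row$d_ou
  )
}

#' Published population ranges of the afferent sample
#'
#' Ranges of the measured and fitted quantities across the experimental
#' sample of 56 afferents: firing rate, frequency ratio, CV, quality factor,
#' harmonic and OU noise SDs, and record length in intervals.
#'
#' @return A tibble with columns `param`, `lower`, `upper`.
#' @export
population_ranges <- function() {
  tibble::tibble(
    param = c("rate_hz", "w", "cv", "Q", "sigma_h", "sigma_ou", "n_isis"),
    lower = c(37.9, 0.40, 0.11, 8.570, 0.129, 0.084, 15000),
    upper = c(77.7, 0.61, 0.31, 29.46, 0.443, 0.303, 50000)
  )
}

#' Sample a surrogate afferent population
#'
#' Draws `n` independent parameter sets uniformly within
#' [population_ranges()] (the joint distribution of the experimental sample
#' is not published, so independence and uniformity are the neutral choice).
#'
#' @param n Number of units (default 56, the experimental sample size).
#' @param seed Optional integer seed.
#' @param tau_ou OU correlation time attached to every unit.
#' @return A tibble with one row per unit: `unit`, `rate_hz`, `w`, `Q`,
#'   `sigma_h`, `sigma_ou`, `tau_ou`, `n_isis`.
#' @export
sample_population <- function(n = 56, seed = NULL, tau_ou = 0.1) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  rg <- population_ranges()
  draw <- function(nm) {
    i <- match(nm, rg$param)
    stats::runif(n, rg$lower[i], rg$upper[i])
  }
  tibble::tibble(
    unit = seq_len(n),
    rate_hz = draw("rate_hz"),
    w = draw("w"),
    Q = draw("Q"),
    sigma_h = draw("sigma_h"),
    sigma_ou = draw("sigma_ou"),
    tau_ou = tau_ou,
    n_isis = round(draw("n_isis"))
  )
}

#' Write a surrogate spike-train dataset to disk
#'
#' Simulates one spike train per parameter set and writes plain-text
#' spike-time files (seconds, one per line) plus a JSON manifest holding the
#' ground-truth parameters and per-unit seeds, so that recovery experiments
#' can be scored against the truth.
#'
#' @param params_df Tibble with columns `w`, `Q`, `sigma_h`, `sigma_ou`
#'   (optionally `tau_ou`, `rate_hz`, `n_isis`, `unit`), e.g. from
#'   [sample_population()].
#' @param n_isis Number of ISIs per unit; overrides a `n_isis` column.
#' @param seed Integer base seed; unit `i` uses `seed + i`.
#' @param out_dir Output directory (created if missing).
#' @param dt Simulator step (canonical units).
#' @return Invisibly, the manifest tibble (also written to
#'   `manifest.json`).
#' @export
surrogate_dataset <- function(params_df, n_isis = NULL, seed = 1,
                              out_dir = ".", dt = 1 / 500) {
  stopifnot(is.data.frame(params_df), nrow(params_df) >= 1)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- purrr::map(seq_len(nrow(params_df)), function(i) {
    row <- as.list(params_df[i, , drop = FALSE])
    p <- as_pif_params(row)
    n <- if (!is.null(n_isis)) n_isis else row$n_isis
    if (is.null(n) || n < 1000) stop("need n_isis >= 1000 per unit")
    seed_i <- seed + i
    st <- simulate_pif(p, n_spikes = n + 1, dt = dt, seed = seed_i)
    unit <- if (!is.null(row$unit)) row$unit else i
    file <- file.path(out_dir, sprintf("unit%03d_spikes.txt", unit))
    write_spike_times(st, file)
    tibble::tibble(
      unit = unit, file = basename(file), seed = seed_i, n_isis = n,
      w = p$w, Q = p$Q, sigma_h = p$sigma_h, sigma_ou = p$sigma_ou,
      tau_ou = p$tau_ou, d_ou = p$D_ou,
      rate_hz = if (is.null(p$rate_hz)) NA_real_ else p$rate_hz
    )
  })
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = FALSE, pretty = TRUE)
  invisible(manifest)
}
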
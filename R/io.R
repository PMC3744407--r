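# Plain-text spike-time files (one timestamp per line, '#' comments) and
# YAML/JSON parameter configurations.

#' Write spike times to a plain-text file
#'
#' One timestamp per line, preceded by `#` provenance comments recording the
#' units and, when known, the firing rate and seed.
#'
#' @param spike_times A [spike_train()] (or numeric vector, assumed
#'   seconds).
#' @param path Output file.
#' @param digits Significant digits written (default 15).
#' @export
write_spike_times <- function(spike_times, path, digits = 15) {
  t <- spike_times_of(spike_times)
  units <- if (is.data.frame(spike_times) && !is.null(attr(spike_times, "units")))
    attr(spike_times, "units") else "seconds"
  p <- if (is.data.frame(spike_times)) attr(spike_times, "params") else NULL
  seed <- if (is.data.frame(spike_times)) attr(spike_times, "seed") else NULL
  hdr <- c(sprintf("# units=%s", units))
  if (!is.null(p) && !is.null(p$rate_hz))
    hdr <- c(hdr, sprintf("# rate_hz=%.6g", p$rate_hz))
  if (!is.null(seed)) hdr <- c(hdr, sprintf("# seed=%d", seed))
  writeLines(c(hdr, formatC(t, digits = digits, format = "g")), path)
  invisible(path)
}

#' Read spike times from a plain-text file
#'
#' Lines starting with `#` are ignored (a `# rate_hz=...` comment, if
#' present, is recorded in the result's attributes). Times must be strictly
#' increasing.
#'
#' @param path Input file.
#' @return A [spike_train()] with units `"seconds"`.
#' @export
read_spike_times <- function(path) {
  lines <- readLines(path)
  comments <- lines[startsWith(trimws(lines), "#")]
  data_lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  times <- as.numeric(data_lines)
  if (anyNA(times)) stop("non-numeric spike time in ", path)
  rate <- NA_real_
  m <- regmatches(comments, regexec("rate_hz=([0-9.eE+-]+)", comments))
  hits <- vapply(m, length, integer(1)) == 2
  if (any(hits)) rate <- as.numeric(m[hits][[1]][2])
  out <- spike_train(times, units = "seconds")
  attr(out, "rate_hz") <- rate
  out
}

#' Write a parameter configuration file
#'
#' Serializes a [pif_params()] object to YAML (or JSON by extension) so that
#' runs are reproducible from a single file.
#'
#' @param params A [pif_params()] object.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @export
write_pif_config <- function(params, path) {
  params <- as_pif_params(params)
  cfg <- list(w = params$w, Q = params$Q, sigma_h = params$sigma_h,
              sigma_ou = params$sigma_ou, tau_ou = params$tau_ou,
              rate_hz = params$rate_hz)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Read a parameter configuration file
#'
#' @param path YAML or JSON file as written by [write_pif_config()].
#' @return A [pif_params()] object.
#' @export
read_pif_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  as_pif_params(cfg)
}
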
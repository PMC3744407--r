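# ggplot2 graphics for the main result types.

#' Plot an ISI histogram against the theoretical density
#'
#' @param spike_times Spike train or ISI sequence (canonical units, or any
#'   units if `params` is `NULL`).
#' @param params Optional [pif_params()]; when supplied the closed-form
#'   density is overlaid (the ISIs are normalized to unit mean first).
#' @param bins Number of histogram bins.
#' @param mode Density mode passed to [isi_density()].
#' @return A ggplot object.
#' @export
plot_isi_density <- function(spike_times, params = NULL, bins = 80,
                             mode = "full") {
  x <- if (is.data.frame(spike_times) && "isi" %in% names(spike_times))
    spike_times[["isi"]] else isis(spike_times)$isi
  if (!is.null(params)) x <- x / mean(x)
  df <- tibble::tibble(isi = x)
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$isi)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::labs(x = "interspike interval", y = "probability density") +
    ggplot2::theme_minimal()
  if (!is.null(params)) {
    d <- isi_density(as_pif_params(params), mode = mode)
    g <- g + ggplot2::geom_line(data = d,
                                ggplot2::aes(x = .data$time, y = .data$density),
                                colour = "firebrick", linewidth = 0.8)
  }
  g
}

#' Plot a serial-correlation series with optional theory overlay
#'
#' @param scc Tibble with columns `lag`, `rho`, optionally `se`.
#' @param params Optional [pif_params()] for the closed-form overlay.
#' @param mode Theory mode passed to [scc_theory()].
#' @return A ggplot object.
#' @export
plot_scc <- function(scc, params = NULL, mode = "general") {
  g <- ggplot2::ggplot(scc, ggplot2::aes(x = .data$lag, y = .data$rho)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "lag k", y = expression(rho[k])) +
    ggplot2::theme_minimal()
  if ("se" %in% names(scc) && !all(is.na(scc$se)))
    g <- g + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$rho - .data$se, ymax = .data$rho + .data$se),
      width = 0, colour = "grey40")
  if (!is.null(params)) {
    th <- tibble::tibble(lag = scc$lag,
                         rho = scc_theory(scc$lag, as_pif_params(params),
                                          mode = mode))
    g <- g + ggplot2::geom_line(data = th, colour = "firebrick")
  }
  g
}

#' Plot a spike-train power spectral density
#'
#' @param psd Tibble from [psd_estimate()].
#' @param fmax Upper frequency limit (defaults to twice the firing rate when
#'   known).
#' @return A ggplot object.
#' @export
plot_psd <- function(psd, fmax = NULL) {
  if (is.null(fmax)) {
    r <- attr(psd, "rate")
    fmax <- if (!is.null(r)) 2.5 * r else max(psd$freq)
  }
  ggplot2::ggplot(dplyr::filter(psd, .data$freq <= fmax),
                  ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "frequency (Hz)", y = "spike-train PSD") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Diagnostic plot of a fitted spike train
#'
#' Shows the measured serial correlations with error bars and the fitted
#' damped-cosine closed form.
#'
#' @param object A `pif_fit` from [extract_parameters()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pif_fit <- function(object, ...) {
  df <- object$scc_fit$fitted
  scc <- object$scc
  g <- plot_scc(scc[scc$lag %in% df$lag, ])
  g + ggplot2::geom_line(data = df,
                         ggplot2::aes(x = .data$lag, y = .data$fit),
                         colour = "firebrick") +
    ggplot2::ggtitle(sprintf("Q = %.2f, w = %.3f, sigma_h = %.3f, D_ou = %.2e",
                             object$Q, object$w, object$sigma_h, object$d_ou))
}
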
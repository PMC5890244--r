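#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a snifflet fit into one row per bin
#'
#' @param x A `snifflet_fit`.
#' @param ... Unused.
#' @return A tibble: `bin`, `u_lo`/`u_hi` (the bin's dilated-phase
#'   support), `psi` (log spikes/s), `var` (marginal posterior variance),
#'   `rate` (spikes/s) and `inhalation` (whether the bin lies in the
#'   inhalation part of the sniff).
#' @export
tidy.snifflet_fit <- function(x, ...) {
  m <- x$D * x$K
  tibble::tibble(
    bin = seq_len(m),
    u_lo = (seq_len(m) - 1) / x$D,
    u_hi = seq_len(m) / x$D,
    psi = x$psi,
    var = x$var,
    rate = exp(x$psi),
    inhalation = seq_len(m) <= x$D
  )
}

#' One-row summary of a snifflet fit
#'
#' @param x A `snifflet_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the model dimensions, dilation scheme,
#'   learned hyperparameters, prior mean, log evidence and data sizes.
#' @method glance snifflet_fit
#' @export
glance.snifflet_fit <- function(x, ...) {
  tibble::tibble(
    D = x$D, K = x$K, scheme = x$scheme, delta = x$delta,
    rho = unname(x$hyper["rho"]),
    length_scale = unname(x$hyper["delta_len"]),
    prior_mean = x$prior_mean,
    log_evidence = x$log_evidence,
    n_sniffs = x$n_sniffs, n_spikes = x$n_spikes,
    constant = x$constant
  )
}

#' Plot a fitted snifflet with its posterior band
#'
#' Firing rate over normalized sniff time, with a band of +/- `k`
#' marginal posterior SDs (log-space band, exponentiated). The inhalation
#' part of the axis is drawn with a heavier underline.
#'
#' @param object A `snifflet_fit`.
#' @param k Band half-width in posterior SDs (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot snifflet_fit
#' @export
autoplot.snifflet_fit <- function(object, k = 1, ...) {
  td <- tidy(object)
  td$u <- (td$u_lo + td$u_hi) / 2
  td$lo <- exp(td$psi - k * sqrt(td$var))
  td$hi <- exp(td$psi + k * sqrt(td$var))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$u, y = .data$rate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::annotate("segment", x = 0, xend = 1, y = 0, yend = 0,
                      linewidth = 2) +
    ggplot2::labs(x = "normalized sniff time (inhalation durations)",
                  y = "firing rate (spikes/s)") +
    ggplot2::theme_minimal()
}

#' Population mean snifflet curves by group and odor
#'
#' @param population The `population` tibble of a
#'   [run_full_analysis()] result.
#' @return A ggplot.
#' @export
plot_population <- function(population) {
  ggplot2::ggplot(population,
                  ggplot2::aes(x = .data$bin, y = .data$mean,
                               color = .data$tagged, fill = .data$tagged)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~odor) +
    ggplot2::labs(x = "snifflet bin", y = "normalized response",
                  color = "tagged", fill = "tagged") +
    ggplot2::theme_minimal()
}

#' Cumulative distributions of response latency by group and odor
#'
#' @param calls The `calls` tibble of a [run_full_analysis()] result
#'   (needs a `tagged` column).
#' @return A ggplot.
#' @export
plot_latency_cdf <- function(calls) {
  d <- calls[!is.na(calls$latency_u), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$latency_u,
                                  color = .data$tagged)) +
    ggplot2::stat_ecdf() +
    ggplot2::facet_wrap(~odor) +
    ggplot2::labs(x = "latency (inhalation durations)",
                  y = "cumulative fraction of cells", color = "tagged") +
    ggplot2::theme_minimal()
}

#' Concentration-category proportions per odor
#'
#' @param categories The `categories` tibble of a
#'   [run_full_analysis()] result.
#' @return A ggplot.
#' @export
plot_categories <- function(categories) {
  ggplot2::ggplot(categories,
                  ggplot2::aes(x = .data$odor, fill = .data$category)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::labs(x = "odor", y = "fraction of cells",
                  fill = "category") +
    ggplot2::theme_minimal()
}
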
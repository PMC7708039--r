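#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a lifetime distribution
#'
#' @param x A `lifetime_distribution`.
#' @param ... Unused.
#' @return A tibble with `tau_ns`, `amplitude` and the normalized
#'   `fractional_amplitude`.
#' @method tidy lifetime_distribution
#' @export
tidy.lifetime_distribution <- function(x, ...) {
  total <- sum(x$amplitude)
  tibble::tibble(
    tau_ns = x$tau_ns,
    amplitude = x$amplitude,
    fractional_amplitude = if (total > 0) x$amplitude / total else 0
  )
}

#' One-row fit summary of a lifetime distribution
#'
#' @param x A `lifetime_distribution`.
#' @param ... Unused.
#' @return A one-row tibble of fit diagnostics.
#' @method glance lifetime_distribution
#' @export
glance.lifetime_distribution <- function(x, ...) {
  d <- attr(x, "diagnostics")
  tibble::tibble(
    reduced_chisq = d$reduced_chisq,
    lambda = d$lambda,
    iterations = d$iterations,
    converged = d$converged,
    background = d$background,
    flux_ratio = d$flux_ratio,
    n_grid = nrow(x)
  )
}

#' Tidy a conformational landscape
#'
#' @param x A `conformational_landscape`.
#' @param ... Unused.
#' @return A tibble with one row per peak.
#' @method tidy conformational_landscape
#' @export
tidy.conformational_landscape <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a conformational landscape
#'
#' @param x A `conformational_landscape`.
#' @param ... Unused.
#' @return A one-row tibble: peak count, donor reference lifetime, and
#'   amplitude-weighted mean FRET.
#' @method glance conformational_landscape
#' @export
glance.conformational_landscape <- function(x, ...) {
  tibble::tibble(
    n_peaks = nrow(x),
    tau_D = attr(x, "tau_D"),
    mean_E = attr(x, "mean_E")
  )
}

#' Plot a decay trace
#'
#' Photon counts against time on a log count scale.
#'
#' @param object A `decay_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot decay_trace
#' @export
autoplot.decay_trace <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ns, y = .data$counts + 1)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ns)", y = "counts + 1") +
    ggplot2::theme_minimal()
}

#' Plot a lifetime distribution
#'
#' Amplitude against lifetime on a log lifetime axis, the natural domain
#' of a maximum-entropy inversion.
#'
#' @param object A `lifetime_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lifetime_distribution
#' @export
autoplot.lifetime_distribution <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau_ns, y = .data$fractional_amplitude)) +
    ggplot2::geom_area(alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lifetime (ns)", y = "fractional amplitude") +
    ggplot2::theme_minimal()
}

#' Plot a conformational landscape
#'
#' One bar per conformational state: fractional population against peak
#' lifetime, annotated with the per-peak FRET efficiency.
#'
#' @param object A `conformational_landscape`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot conformational_landscape
#' @export
autoplot.conformational_landscape <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(signif(.data$center_ns, 3)),
    y = .data$fractional_population
  )) +
    ggplot2::geom_col(alpha = 0.8) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("E = %.2f", .data$E_peak)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(x = "peak lifetime (ns)", y = "fractional population") +
    ggplot2::theme_minimal()
}

#' Plot a descriptor series
#'
#' Per-model values with the block-averaged mean and its uncertainty band.
#'
#' @param object A `descriptor_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot descriptor_series
#' @export
autoplot.descriptor_series <- function(object, ...) {
  blk <- attr(object, "block")
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = blk$mean, linetype = 2) +
    ggplot2::labs(
      x = "model", y = sprintf("%s (%s)", attr(object, "name"), attr(object, "units"))
    ) +
    ggplot2::theme_minimal()
  if (is.finite(blk$block_sd)) {
    p <- p + ggplot2::annotate("rect",
      xmin = -Inf, xmax = Inf,
      ymin = blk$mean - blk$block_sd, ymax = blk$mean + blk$block_sd,
      alpha = 0.15
    )
  }
  p
}
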
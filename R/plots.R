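# ggplot2 visualisations for each result type.

#' Plot a catalytic-distance / interaction-energy landscape
#'
#' Scatter of sampled poses (distance to the catalytic anchor vs interaction
#' energy) with the lower envelope and the distance cut-off line, the
#' standard read-out of induced-fit landscape screening.
#'
#' @param trajectory A trajectory tibble from [run_simulation()].
#' @param cutoff Catalytic distance cut-off to draw, Angstrom.
#' @param bin_width Envelope bin width, Angstrom.
#' @return A ggplot object.
#' @export
plot_landscape <- function(trajectory, cutoff = 4.0, bin_width = 0.25) {
  prof <- build_profile(trajectory, bin_width = bin_width)
  ggplot2::ggplot(trajectory,
                  ggplot2::aes(x = .data$catalytic_distance,
                               y = .data$interaction_energy)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8, colour = "grey30") +
    ggplot2::geom_line(data = prof$envelope,
                       ggplot2::aes(x = .data$distance, y = .data$energy),
                       colour = "steelblue", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "catalytic distance (Å)",
                  y = "interaction energy (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_landscape
#' @param object,... Autoplot arguments.
#' @export
autoplot.trajectory <- function(object, ...) plot_landscape(object, ...)

#' Plot a Michaelis-Menten fit
#'
#' @param fit An `mm_fit` object.
#' @return A ggplot object: observed rates and the fitted saturation curve.
#' @export
plot_mm_fit <- function(fit) {
  dat <- fit$data
  grid <- tibble(substrate_mM = seq(min(dat$substrate_mM) / 2,
                                    max(dat$substrate_mM) * 1.1,
                                    length.out = 200))
  grid$rate_per_s <- fit$kcat * grid$substrate_mM / (fit$km + grid$substrate_mM)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$substrate_mM,
                                    y = .data$rate_per_s)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "[substrate] (mM)", y = "rate (1/s)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_mm_fit
#' @param object,... Autoplot arguments.
#' @export
autoplot.mm_fit <- function(object, ...) plot_mm_fit(object)

#' Plot a melt curve with its derivative peak
#'
#' @param curve A melt-curve tibble.
#' @return A ggplot object with the melting temperature marked.
#' @export
plot_melt_curve <- function(curve) {
  tm <- tm_from_melt(curve)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$temperature_c,
                                           y = .data$fluorescence)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "temperature (°C)", y = "fluorescence (a.u.)") +
    ggplot2::theme_minimal()
  if (isTRUE(tm$has_transition)) {
    p <- p + ggplot2::geom_vline(xintercept = tm$tm, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' @rdname plot_melt_curve
#' @param object,... Autoplot arguments.
#' @export
autoplot.melt_curve <- function(object, ...) plot_melt_curve(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
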
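# Diagnostic figures.  All plot methods return ggplot objects.

#' @export
autoplot.event_log <- function(object, ...) {
  r <- object$events[object$events$event_type == "reaction", ]
  df <- tibble::tibble(step = c(0, r$step), count = seq(0, nrow(r)))
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$count)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "simulation step", y = "cumulative tracer reactions",
                  title = sprintf("p = %g", object$config$params$crossing_prob))
}

#' @export
autoplot.burst_partition <- function(object, ...) {
  b <- object$bursts
  ggplot2::ggplot(b) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$first_step, xend = .data$last_step,
                                       y = .data$amplitude, yend = .data$amplitude),
                          linewidth = 2) +
    ggplot2::geom_point(ggplot2::aes(.data$first_step, .data$amplitude)) +
    ggplot2::labs(x = "simulation step", y = "burst amplitude",
                  title = sprintf("%d bursts, tau_crit = %g steps",
                                  nrow(b), object$tau_crit))
}

#' @export
autoplot.escape_spectrum <- function(object, ...) {
  tm <- object$mean
  tt <- seq(tm / 50, 6 * tm, length.out = 300)
  df <- tibble::tibble(
    t = rep(tt, 2),
    density = c(escape_density(object, tt), exp(-tt / tm) / tm),
    which = rep(c("spectrum", "single exponential"), each = length(tt)))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$density, linetype = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time", y = "escape-time density",
                  title = sprintf("kappa = %.3g", object$params$kappa))
}

#' Mean squared displacement diagnostic plot
#'
#' Log-log MSD versus lag with the free-diffusion reference line
#' MSD = lag (in lattice units), on which the crossover from microscopic
#' to hop-limited diffusion is visible.
#'
#' @param msd Tibble from [estimate_msd()].
#' @return A ggplot object.
#' @export
plot_msd <- function(msd) {
  ggplot2::ggplot(msd, ggplot2::aes(.data$lag, .data$msd)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag (steps)", y = expression(MSD ~ (a^2)))
}
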
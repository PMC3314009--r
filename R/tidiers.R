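#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for reactburst result objects
#'
#' `tidy()` returns the per-element table of a result (bursts of a
#' partition, modes of an escape spectrum, events of a log); `glance()`
#' returns a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name reactburst-tidiers
NULL

#' @rdname reactburst-tidiers
#' @export
tidy.burst_partition <- function(x, ...) x$bursts

#' @rdname reactburst-tidiers
#' @export
glance.burst_partition <- function(x, ...) {
  tibble::tibble(n_bursts = nrow(x$bursts),
                 mean_amplitude = if (nrow(x$bursts)) mean(x$bursts$amplitude) else NA_real_,
                 n_gaps = nrow(x$gaps),
                 mean_gap = if (nrow(x$gaps)) mean(x$gaps$duration) else NA_real_,
                 tau_crit = x$tau_crit, convention = x$convention)
}

#' @rdname reactburst-tidiers
#' @export
tidy.escape_spectrum <- function(x, ...) {
  tibble::tibble(rate = x$rates, weight = x$weights)
}

#' @rdname reactburst-tidiers
#' @export
glance.escape_spectrum <- function(x, ...) {
  tibble::tibble(mean_escape = x$mean, modes_per_axis = x$K,
                 weight_sum = sum(x$weights), kappa = x$params$kappa)
}

#' @rdname reactburst-tidiers
#' @export
tidy.event_log <- function(x, ...) x$events

#' @rdname reactburst-tidiers
#' @export
glance.event_log <- function(x, ...) {
  nr <- sum(x$events$event_type == "reaction")
  tibble::tibble(n_reactions = nr, n_steps = x$n_steps,
                 reaction_rate = nr / x$n_steps,
                 tracer_monomer_fraction = x$tracer_monomer_fraction,
                 crossing_prob = x$config$params$crossing_prob)
}

#' @rdname reactburst-tidiers
#' @export
glance.confinement_params <- function(x, ...) {
  tibble::tibble(d_micro = x$d_micro, d_macro = x$d_macro,
                 permeability = x$permeability, kappa = x$kappa,
                 ell_c = x$ell_c, diffusion_ratio = diffusion_ratio(x))
}
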
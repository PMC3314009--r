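#' Run the kinetic Monte Carlo simulation
#'
#' Simulates N random walkers (monomers and dimers obey the same step rule)
#' on the compartmentalized lattice for `n_steps` steps.  Each step proceeds
#' in fixed phases: (1) every walker draws a direction from its site's step
#' distribution and all move synchronously; (2) dimers whose scheduled
#' lifetime expires split into two monomers on the dimer's site (the pair
#' may not re-react within the dissociation step); (3) every site occupied
#' by two or more free monomers pairs them uniformly at random and each pair
#' dimerizes with probability p_r, drawing an exponential lifetime rounded
#' up to whole steps; (4) reaction and dissociation events of the labeled
#' tracer are appended to the event log.  Monomer-dimer and dimer-dimer
#' co-occupancies are inert, and any number of walkers may share a site.
#'
#' All randomness flows through R's generator in a fixed order, so identical
#' seed and configuration give a bit-identical event log.
#'
#' @param config A [sim_config()].
#' @param record `"tracer"` (default) records only the tracer's events;
#'   `"all"` additionally records every reaction in the system with its
#'   compartment, as needed for per-compartment local rates.
#' @param track_trajectory If > 0, the tracer's unwrapped displacement is
#'   recorded every `track_trajectory` steps.
#' @return An `event_log` object: tibble `events` with columns `step`,
#'   `event_type` ("reaction"/"dissociation"), `partner_id`, `x`, `y`,
#'   `comp_x`, `comp_y`; the configuration; total steps; the tracer's
#'   long-run monomer fraction; optionally `all_events` and `trajectory`.
#' @examples
#' cfg <- sim_config(lattice_spec(60, 20), sim_params(0.25, n_steps = 2e4, seed = 7))
#' log <- simulate_reactions(cfg)
#' head(log$events)
#' @export
simulate_reactions <- function(config, record = c("tracer", "all"),
                               track_trajectory = 0) {
  stopifnot(inherits(config, "sim_config"))
  record <- match.arg(record)
  sp <- config$spec; pm <- config$params
  set.seed(pm$seed)
  raw <- engine_run_kmc(sp$side_sites, sp$compartment_sites, pm$crossing_prob,
                        pm$reaction_prob,
                        pm$mean_dimer_lifetime / sp$timestep,
                        pm$n_particles, pm$n_steps, pm$tracer_id,
                        record == "all", as.integer(track_trajectory))
  if (!raw$conservation_ok)
    stop("internal error: particle conservation violated")  # nocov
  ev <- raw$events
  events <- tibble::tibble(
    step = ev[, 1],
    event_type = c("reaction", "dissociation")[ev[, 2]],
    partner_id = as.integer(ev[, 3]),
    x = as.integer(ev[, 4]), y = as.integer(ev[, 5]))
  events <- dplyr::bind_cols(events, compartment_index(events$x, events$y, sp))
  out <- list(events = events, config = config, n_steps = pm$n_steps,
              tracer_monomer_fraction = raw$tracer_monomer_steps / pm$n_steps)
  if (record == "all") {
    ae <- raw$all_events
    all_events <- tibble::tibble(step = ae[, 1], id = as.integer(ae[, 2]),
                                 partner_id = as.integer(ae[, 3]),
                                 x = as.integer(ae[, 4]), y = as.integer(ae[, 5]))
    out$all_events <- dplyr::bind_cols(all_events,
                                       compartment_index(all_events$x, all_events$y, sp))
  }
  if (track_trajectory > 0) {
    tr <- raw$trajectory
    out$trajectory <- tibble::tibble(step = tr[, 1], dx = tr[, 2], dy = tr[, 3])
  }
  structure(out, class = "event_log")
}

#' @exportS3Method base::print
print.event_log <- function(x, ...) {
  nr <- sum(x$events$event_type == "reaction")
  cat(sprintf("<event_log> %d tracer reactions over %g steps (rate %.3g/step), monomer fraction %.3f\n",
              nr, x$n_steps, nr / x$n_steps, x$tracer_monomer_fraction))
  invisible(x)
}

#' Simulate independent non-reacting walkers
#'
#' Releases `n_walkers` independent walkers uniformly on the lattice and
#' records their unwrapped displacements every `thin` steps, for mean
#' squared displacement analysis.
#'
#' @param spec A [lattice_spec()].
#' @param p Crossing probability.
#' @param n_walkers Number of walkers.
#' @param n_steps Steps to simulate.
#' @param thin Sampling interval in steps.
#' @param seed Seed.
#' @return A `walker_paths` object: displacement matrices `x`, `y` (rows =
#'   sample times starting at 0, columns = walkers), `thin`, and the spec.
#' @export
simulate_walkers <- function(spec, p, n_walkers, n_steps, thin = 1, seed = 1) {
  stopifnot(inherits(spec, "lattice_spec"))
  set.seed(seed)
  raw <- engine_walker_paths(spec$side_sites, spec$compartment_sites, p,
                             n_walkers, n_steps, as.integer(thin))
  structure(list(x = raw$x, y = raw$y, thin = as.integer(thin), spec = spec,
                 p = p), class = "walker_paths")
}

#' Sample dimer lifetimes in whole steps
#'
#' Lifetimes are exponential with mean `tau_d`, divided by the time step and
#' rounded up to the nearest integer, so every dimer lives at least one
#' step.  The mean of the rounded lifetime is 1/(1 - exp(-dt/tau_d)) steps
#' (see [dimer_lifetime_mean()]).
#'
#' @param n Number of draws.
#' @param tau_d Mean lifetime (time units).
#' @param dt Simulation time step.
#' @return Integer vector of lifetimes in steps (>= 1).
#' @export
sample_dimer_lifetime <- function(n, tau_d, dt = 1) {
  stopifnot(tau_d > 0, dt > 0)
  pmax(1L, as.integer(ceiling(stats::rexp(n, rate = 1 / tau_d) / dt)))
}

#' @rdname sample_dimer_lifetime
#' @return `dimer_lifetime_mean()`: the exact mean of the ceiling-rounded
#'   exponential lifetime, in steps.
#' @export
dimer_lifetime_mean <- function(tau_d, dt = 1) 1 / (1 - exp(-dt / tau_d))

#' Mean squared displacement of simulated walkers
#'
#' Time- and ensemble-averaged MSD over all start times at the requested
#' lags, in units of the squared lattice spacing.
#'
#' @param paths A [simulate_walkers()] result or an event-log trajectory
#'   (tibble with `step`, `dx`, `dy`).
#' @param lags Lags in steps; must be multiples of the sampling interval and
#'   smaller than the trajectory span.
#' @return Tibble with `lag` (steps), `msd`, and the number of averaged
#'   displacement pairs `n_obs`.
#' @export
estimate_msd <- function(paths, lags) {
  if (inherits(paths, "walker_paths")) {
    X <- paths$x; Y <- paths$y; thin <- paths$thin
  } else {
    stopifnot(is.data.frame(paths), all(c("step", "dx", "dy") %in% names(paths)))
    X <- cbind(paths$dx); Y <- cbind(paths$dy)
    thin <- if (nrow(paths) > 1) paths$step[2] - paths$step[1] else 1
  }
  nt <- nrow(X)
  lags <- as.integer(lags)
  if (any(lags < thin | lags %% thin != 0))
    stop("lags must be positive multiples of the sampling interval (", thin, ")", call. = FALSE)
  rows <- lags %/% thin
  if (any(rows >= nt)) stop("lag exceeds trajectory length", call. = FALSE)
  msd <- vapply(rows, function(r) {
    i <- seq_len(nt - r)
    mean((X[i + r, , drop = FALSE] - X[i, , drop = FALSE])^2 +
         (Y[i + r, , drop = FALSE] - Y[i, , drop = FALSE])^2)
  }, numeric(1))
  n_obs <- (nt - rows) * ncol(X)
  tibble::tibble(lag = lags, msd = msd, n_obs = n_obs)
}

#' Estimate the microscopic or effective diffusion coefficient
#'
#' In the `"micro"` regime the coefficient is taken from the shortest
#' available lags (default: lags up to 2 steps, fitted through the origin).
#' The walker moves one site every step, so the one-step MSD equals the
#' squared spacing exactly and determines D_micro = a^2/(4 dt) without
#' contamination from compartment curvature, which already depresses the
#' apparent slope at lags well below the escape time.  In the `"macro"`
#' regime the coefficient is the least-squares slope (with intercept, since
#' confined MSD carries a positive offset) over lags of at least 20 times
#' the single-molecule escape time, where hop diffusion is the only
#' remaining transport mode.
#'
#' @param msd A tibble from [estimate_msd()].
#' @param regime `"micro"` or `"macro"`.
#' @param escape_steps Single-molecule mean escape time in steps (required
#'   for the macro regime; see [mean_escape_times()]).
#' @param window Optional explicit lag range `c(min, max)` overriding the
#'   defaults.
#' @return The diffusion coefficient in a^2/dt units, with the used lag
#'   window as attribute `"window"`.
#' @export
estimate_diffusion <- function(msd, regime = c("micro", "macro"),
                               escape_steps = NULL, window = NULL) {
  regime <- match.arg(regime)
  if (is.null(window)) {
    window <- if (regime == "micro") c(1, 2)
              else {
                if (is.null(escape_steps))
                  stop("`escape_steps` is required for the macro regime", call. = FALSE)
                c(20 * escape_steps, Inf)
              }
  }
  sel <- msd$lag >= window[1] & msd$lag <= window[2]
  if (sum(sel) < 1 || (regime == "macro" && sum(sel) < 2))
    stop("no (or too few) MSD lags inside the ", regime, " window", call. = FALSE)
  d <- msd[sel, ]
  slope <- if (regime == "micro") {
    sum(d$lag * d$msd) / sum(d$lag^2)            # through the origin
  } else {
    unname(stats::coef(stats::lm(msd ~ lag, data = d))[2])
  }
  structure(slope / 4, window = range(d$lag))
}
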
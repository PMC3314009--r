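#' Define the compartmentalized lattice geometry
#'
#' The simulation region is a periodic square lattice of `side_sites` x
#' `side_sites` sites with spacing `spacing`, partitioned into square
#' compartments of `compartment_sites` sites per side by permeable barriers.
#' Barriers live on the lines *between* sites, so every site belongs to
#' exactly one compartment and the periodic wrap seam coincides with a
#' compartment boundary.
#'
#' @param side_sites Sites per side of the periodic region (L). Must be an
#'   exact multiple of `compartment_sites`.
#' @param compartment_sites Sites per compartment side (n), at least 2. With
#'   a single site per compartment the step rule cannot be normalized for a
#'   crossing probability other than 1/4, so n = 1 is rejected.
#' @param spacing Physical length of one lattice step (a). Defaults to 1
#'   lattice unit.
#' @param timestep Physical duration of one simulation step (dt). Defaults
#'   to 1 time unit.
#' @return A `lattice_spec` object (list with the fields above plus
#'   `compartments_per_side`).
#' @examples
#' lattice_spec(200, 20)
#' @export
lattice_spec <- function(side_sites, compartment_sites, spacing = 1, timestep = 1) {
  stopifnot(length(side_sites) == 1, length(compartment_sites) == 1)
  side_sites <- as.integer(side_sites)
  compartment_sites <- as.integer(compartment_sites)
  if (compartment_sites < 2L)
    stop("`compartment_sites` must be >= 2: single-site compartments make the step rule degenerate", call. = FALSE)
  if (side_sites < compartment_sites || side_sites %% compartment_sites != 0L)
    stop(sprintf("`side_sites` (%d) must be a positive multiple of `compartment_sites` (%d)",
                 side_sites, compartment_sites), call. = FALSE)
  if (!is.finite(spacing) || spacing <= 0) stop("`spacing` must be > 0", call. = FALSE)
  if (!is.finite(timestep) || timestep <= 0) stop("`timestep` must be > 0", call. = FALSE)
  structure(list(side_sites = side_sites,
                 compartment_sites = compartment_sites,
                 spacing = as.numeric(spacing), timestep = as.numeric(timestep),
                 compartments_per_side = side_sites %/% compartment_sites),
            class = "lattice_spec")
}

#' Simulation parameters for the reaction-diffusion run
#'
#' @param crossing_prob Barrier crossing probability p per attempt, in
#'   \[0, 0.25\]. At p = 0.25 the walk is the free isotropic walk (no
#'   confinement); larger values would make barrier directions preferred and
#'   are rejected.
#' @param reaction_prob Dimerization probability p_r per co-occupancy step,
#'   in (0, 1\].
#' @param mean_dimer_lifetime Mean dimer lifetime tau_d (in time units; with
#'   the default `timestep = 1`, in steps). Lifetimes are exponential,
#'   rounded up to whole steps.
#' @param n_particles Number of molecules N (>= 1).
#' @param n_steps Number of simulation steps.
#' @param seed Integer seed; identical seed and configuration give a
#'   bit-identical event log.
#' @param tracer_id Id (0-based) of the labeled tracer molecule.
#' @param inter_reaction_convention How the waiting time between successive
#'   tracer reactions is measured: from the preceding dissociation
#'   (`"dissociation_to_reaction"`, the default, isolating the search time)
#'   or from the preceding reaction (`"reaction_to_reaction"`, which
#'   includes the dimer dwell).
#' @return A `sim_params` object.
#' @export
sim_params <- function(crossing_prob, reaction_prob = 1, mean_dimer_lifetime = 100,
                       n_particles = 10, n_steps = 1e6, seed = 1L, tracer_id = 0L,
                       inter_reaction_convention = c("dissociation_to_reaction",
                                                     "reaction_to_reaction")) {
  if (!is.finite(crossing_prob) || crossing_prob < 0 || crossing_prob > 0.25)
    stop("`crossing_prob` must lie in [0, 0.25] (0.25 is the free-diffusion value)", call. = FALSE)
  if (!is.finite(reaction_prob) || reaction_prob <= 0 || reaction_prob > 1)
    stop("`reaction_prob` must lie in (0, 1]", call. = FALSE)
  if (!is.finite(mean_dimer_lifetime) || mean_dimer_lifetime <= 0)
    stop("`mean_dimer_lifetime` must be > 0", call. = FALSE)
  if (n_particles < 1) stop("`n_particles` must be >= 1", call. = FALSE)
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  if (tracer_id < 0 || tracer_id >= n_particles)
    stop("`tracer_id` must name one of the particles (0-based)", call. = FALSE)
  structure(list(crossing_prob = as.numeric(crossing_prob),
                 reaction_prob = as.numeric(reaction_prob),
                 mean_dimer_lifetime = as.numeric(mean_dimer_lifetime),
                 n_particles = as.integer(n_particles), n_steps = as.numeric(n_steps),
                 seed = as.integer(seed), tracer_id = as.integer(tracer_id),
                 inter_reaction_convention = match.arg(inter_reaction_convention)),
            class = "sim_params")
}

#' Validate and combine geometry and parameters into one configuration
#'
#' Checks every invariant of the geometry and the parameters and populates
#' derived quantities: compartments per side, walker density per compartment
#' (rho), lattice sites per particle, and the default burst threshold
#' `tau_crit` (left `NULL` here and filled from the escape-time theory by
#' [default_tau_crit()] when first needed).
#'
#' @param spec A [lattice_spec()].
#' @param params A [sim_params()].
#' @param tau_crit Optional burst-segmentation threshold override (steps).
#' @return A `sim_config` object.
#' @examples
#' cfg <- sim_config(lattice_spec(200, 20), sim_params(0.25, n_steps = 1e4))
#' cfg$density_per_compartment
#' @export
sim_config <- function(spec, params, tau_crit = NULL) {
  stopifnot(inherits(spec, "lattice_spec"), inherits(params, "sim_params"))
  if (!is.null(tau_crit) && tau_crit <= 0) stop("`tau_crit` must be positive", call. = FALSE)
  n_comp <- spec$compartments_per_side^2
  if (!is.null(tau_crit)) tau_crit <- as.numeric(tau_crit)
  structure(list(spec = spec, params = params, tau_crit = tau_crit,
                 density_per_compartment = params$n_particles / n_comp,
                 sites_per_particle = spec$side_sites^2 / params$n_particles),
            class = "sim_config")
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> L=%d n=%d (%d x %d compartments), p=%g, p_r=%g, tau_d=%g\n",
              x$spec$side_sites, x$spec$compartment_sites,
              x$spec$compartments_per_side, x$spec$compartments_per_side,
              x$params$crossing_prob, x$params$reaction_prob,
              x$params$mean_dimer_lifetime))
  cat(sprintf("  N=%d (%g per compartment, %g sites per particle), %g steps, seed %d\n",
              x$params$n_particles, x$density_per_compartment,
              x$sites_per_particle, x$params$n_steps, x$params$seed))
  invisible(x)
}

.directions <- c("+x", "-x", "+y", "-y")

#' Compartment index of a lattice position
#'
#' @param x,y Integer site coordinates in \[0, L).
#' @param spec A [lattice_spec()].
#' @return A tibble with columns `comp_x`, `comp_y` (0-based compartment
#'   indices), one row per input position.
#' @export
compartment_index <- function(x, y, spec) {
  n <- spec$compartment_sites
  tibble::tibble(comp_x = as.integer(x %/% n), comp_y = as.integer(y %/% n))
}

#' Does a unit move cross a compartment barrier?
#'
#' Barriers separate site column (or row) kn - 1 from kn for every integer
#' k, including the periodic seam between column L - 1 and 0.  The relation
#' is symmetric: crossing A to B is a barrier move iff B to A is.
#'
#' @inheritParams compartment_index
#' @param direction One of `"+x"`, `"-x"`, `"+y"`, `"-y"`.
#' @export
is_barrier_move <- function(x, y, direction, spec) {
  n <- spec$compartment_sites
  switch(match.arg(direction, .directions),
         "+x" = (x + 1L) %% n == 0L,
         "-x" = x %% n == 0L,
         "+y" = (y + 1L) %% n == 0L,
         "-y" = y %% n == 0L)
}

#' Per-direction step probabilities at a site
#'
#' Interior sites step in each of the 4 directions with probability 1/4.
#' A site with b adjacent barrier directions (b = 1 on compartment edges,
#' b = 2 in corners) crosses each barrier with probability p and takes each
#' of the remaining 4 - b directions with probability (1 - b p)/(4 - b); the
#' walker always moves.  At p = 0.25 every site reduces to the isotropic
#' free walk.
#'
#' @inheritParams compartment_index
#' @param p Barrier crossing probability in \[0, 0.25\].
#' @return Named numeric vector of probabilities over `c("+x","-x","+y","-y")`,
#'   summing to 1.
#' @examples
#' spec <- lattice_spec(200, 20)
#' step_distribution(5, 5, spec, 0.01)    # interior: 1/4 each
#' step_distribution(19, 5, spec, 0.01)   # edge: barrier direction gets 0.01
#' @export
step_distribution <- function(x, y, spec, p) {
  if (p < 0 || p > 0.25) stop("`p` must lie in [0, 0.25]", call. = FALSE)
  bar <- vapply(.directions, function(d) is_barrier_move(x, y, d, spec), logical(1))
  b <- sum(bar)
  pr <- ifelse(bar, p, (1 - b * p) / (4 - b))
  names(pr) <- .directions
  pr
}

#' Take one lattice step with periodic wrapping
#'
#' @inheritParams is_barrier_move
#' @return Named integer vector `c(x =, y =)` of the new position.
#' @export
apply_move <- function(x, y, direction, spec) {
  L <- spec$side_sites
  switch(match.arg(direction, .directions),
         "+x" = c(x = (x + 1L) %% L, y = y),
         "-x" = c(x = (x - 1L) %% L, y = y),
         "+y" = c(x = x, y = (y + 1L) %% L),
         "-y" = c(x = x, y = (y - 1L) %% L))
}

#' Crossing probability at which barriers vanish
#'
#' Solves, from the step-probability rule itself, for the crossing
#' probability at which every site's step distribution becomes uniform over
#' the four directions -- i.e. the value at which the compartmentalized walk
#' is indistinguishable from free diffusion.  The root is located
#' numerically on the edge-site class and verified on the corner-site class.
#'
#' @param spec A [lattice_spec()]; geometry only sets which site classes
#'   exist.
#' @param tol Root-finding tolerance.
#' @return The crossing probability (a number; 0.25 for this step rule).
#' @export
uniform_crossing_prob <- function(spec = lattice_spec(8, 4), tol = 1e-12) {
  n <- spec$compartment_sites
  edge <- if (n > 2) c(n - 1L, 1L) else c(n - 1L, 0L)   # n = 2: corners only
  # difference between the barrier-direction and a non-barrier-direction prob
  f <- function(p) {
    d <- step_distribution(edge[1], edge[2], spec, p)
    d[["+x"]] - d[["-x"]]
  }
  root <- stats::uniroot(f, c(0, 0.25), tol = tol)$root
  corner <- step_distribution(n - 1L, n - 1L, spec, root)
  if (max(abs(corner - 0.25)) > 1e-8)
    stop("no single crossing probability makes all site classes uniform")
  root
}
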
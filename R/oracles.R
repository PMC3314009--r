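# Exact reference computations on small lattices.  These gate the closed-form
# theory layer and the stochastic engine: an absorbing chain for the escape
# problem, a parity-restricted product chain for pair re-encounter, a
# homogenization corrector for the effective diffusion coefficient, and a
# brute-force two-particle burst simulator.

site_index <- function(x, y, n) 1L + x + n * y

transition_matrix_compartment <- function(n, p, boundary = c("absorb", "reflect")) {
  boundary <- match.arg(boundary)
  spec <- lattice_spec(n, n)
  S <- n * n
  Tm <- matrix(0, S, S)
  for (x in 0:(n - 1)) for (y in 0:(n - 1)) {
    i <- site_index(x, y, n)
    pr <- step_distribution(x, y, spec, if (boundary == "reflect") 0 else p)
    tos <- list(`+x` = c(x + 1, y), `-x` = c(x - 1, y),
                `+y` = c(x, y + 1), `-y` = c(x, y - 1))
    for (d in names(tos)) {
      tx <- tos[[d]][1]; ty <- tos[[d]][2]
      if (tx < 0 || tx >= n || ty < 0 || ty >= n) next   # absorbed / forbidden
      j <- site_index(tx, ty, n)
      Tm[i, j] <- Tm[i, j] + pr[[d]]
    }
  }
  Tm
}

#' Exact escape-time distribution from one compartment
#'
#' Builds the absorbing Markov chain on the n x n compartment sites (barrier
#' crossings lead to a single absorbing "escaped" state) and returns the
#' exact escape-step pmf by iterated application of the transient block,
#' together with the exact mean escape time from the fundamental matrix,
#' both averaged over a uniform initial site.
#'
#' @param n Compartment side in sites (n <= 30 keeps the chain small).
#' @param p Crossing probability in (0, 0.25\].
#' @param max_steps Steps to tabulate; defaults to 25 times the mean.
#' @return List with `mean` (steps), `pmf` (tibble `step`, `prob`), and the
#'   probability mass beyond `max_steps` in `tail_mass`.
#' @examples
#' exact_escape_pmf(2, 0.05)$mean   # geometric: 1/(2p) = 10
#' @export
exact_escape_pmf <- function(n, p, max_steps = NULL) {
  stopifnot(n >= 2, n <= 30, p > 0, p <= 0.25)
  Q <- transition_matrix_compartment(n, p, "absorb")
  S <- n * n
  m <- solve(diag(S) - Q, rep(1, S))
  mean_esc <- mean(m)
  if (is.null(max_steps)) max_steps <- ceiling(25 * mean_esc)
  mu <- rep(1 / S, S)
  pmf <- numeric(max_steps)
  for (t in seq_len(max_steps)) {
    mu2 <- as.vector(mu %*% Q)
    pmf[t] <- sum(mu) - sum(mu2)
    mu <- mu2
  }
  list(mean = mean_esc,
       pmf = tibble::tibble(step = seq_len(max_steps), prob = pmf),
       tail_mass = sum(mu))
}

#' Exact mean pair re-encounter time under reflecting walls
#'
#' Two independent walkers in one compartment with reflecting walls, both
#' released on the same uniformly chosen site; the mean first co-occupancy
#' time (counted from the next step) is solved on the product chain.  Since
#' both walkers move every step, the parity of their relative displacement
#' is conserved; the solve is restricted to the reachable even-parity
#' off-diagonal states.
#'
#' @param n Compartment side (n <= 6: the product chain has n^4 states).
#' @return Mean re-encounter time in steps.
#' @export
exact_pair_reencounter <- function(n) {
  stopifnot(n >= 2, n <= 6)
  Tm <- Matrix::Matrix(transition_matrix_compartment(n, 0, "reflect"), sparse = TRUE)
  S <- n * n
  TT <- Matrix::kronecker(Tm, Tm)
  xy <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  parity <- (xy$x + xy$y) %% 2
  i_of <- rep(seq_len(S), each = S); j_of <- rep(seq_len(S), times = S)
  even <- (parity[i_of] + parity[j_of]) %% 2 == 0
  diag_states <- i_of == j_of
  keep <- even & !diag_states
  Q <- TT[keep, keep]
  m_off <- Matrix::solve(Matrix::Diagonal(sum(keep)) - Q, rep(1, sum(keep)))
  mfull <- numeric(S * S); mfull[keep] <- as.vector(m_off)
  t_s <- 1 + as.vector(TT[which(diag_states), , drop = FALSE] %*% mfull)
  mean(t_s)
}

#' Exact effective diffusion coefficient of the compartmentalized walk
#'
#' Computes the long-time diffusion coefficient of the hop rule exactly by
#' homogenization on one n x n periodic cell: the stationary distribution,
#' the corrector solving the Poisson equation for the x-displacement, and
#' the central-limit variance of the displacement functional.
#'
#' @param n Compartment side in sites.
#' @param p Crossing probability.
#' @return D_macro in a^2/dt units (0.25 at p = 0.25).
#' @export
exact_effective_diffusion <- function(n, p) {
  stopifnot(n >= 2, p >= 0, p <= 0.25)
  spec <- lattice_spec(n, n)
  S <- n * n
  P <- matrix(0, S, S); PDx <- matrix(0, S, S)
  for (x in 0:(n - 1)) for (y in 0:(n - 1)) {
    i <- site_index(x, y, n)
    pr <- step_distribution(x, y, spec, p)
    tos <- list(`+x` = c(x + 1, y, 1), `-x` = c(x - 1, y, -1),
                `+y` = c(x, y + 1, 0), `-y` = c(x, y - 1, 0))
    for (d in names(tos)) {
      j <- site_index(tos[[d]][1] %% n, tos[[d]][2] %% n, n)
      P[i, j] <- P[i, j] + pr[[d]]
      PDx[i, j] <- PDx[i, j] + pr[[d]] * tos[[d]][3]
    }
  }
  ev <- eigen(t(P))
  pi0 <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi0 <- pi0 / sum(pi0)
  b <- rowSums(PDx)
  v <- sum(pi0 * b)
  A <- diag(S) - P; A[1, ] <- 0; A[1, 1] <- 1   # pin chi[1] = 0
  rhs <- b - v; rhs[1] <- 0
  chi <- solve(A, rhs)
  # variance sum per direction (at n = 2 opposite moves reach the same cell
  # state, so transitions must not be merged here)
  s2 <- 0
  for (x in 0:(n - 1)) for (y in 0:(n - 1)) {
    i <- site_index(x, y, n)
    pr <- step_distribution(x, y, spec, p)
    tos <- list(`+x` = c(x + 1, y, 1), `-x` = c(x - 1, y, -1),
                `+y` = c(x, y + 1, 0), `-y` = c(x, y - 1, 0))
    for (d in names(tos)) {
      j <- site_index(tos[[d]][1] %% n, tos[[d]][2] %% n, n)
      s2 <- s2 + pi0[i] * pr[[d]] * (tos[[d]][3] + chi[j] - chi[i])^2
    }
  }
  s2 / 2
}

#' Brute-force two-particle burst statistics
#'
#' Releases a freshly dissociated pair on a uniformly chosen site of the
#' center compartment of a 3 x 3-compartment torus and follows it until the
#' two walkers occupy different compartments, repeating `reps` times.
#' Counts encounters (co-occupancies), reactions (probability `p_r` per
#' encounter, with an exponential dimer dwell before the in-place
#' dissociation), and dissociation-to-outcome legs.  This is the empirical
#' reference for the fugitive probability, the mean number of encounters
#' per burst, and the burst amplitude distribution.
#'
#' @param n Compartment side in sites.
#' @param p Crossing probability.
#' @param p_r Reaction probability per encounter.
#' @param tau_d Mean dimer lifetime in steps.
#' @param reps Number of bursts.
#' @param seed Seed.
#' @return List with `p_fug`, `mean_encounters`, `mean_amplitude`, and the
#'   per-burst `amplitude` vector.
#' @export
two_particle_burst_sim <- function(n, p, p_r = 1, tau_d = 100, reps = 20000,
                                   seed = 1L) {
  stopifnot(n >= 2, p > 0, p <= 0.25, reps >= 1)
  set.seed(seed)
  res <- engine_pair_burst(n, p, p_r, tau_d, as.integer(reps))
  list(p_fug = res$p_fug, mean_encounters = res$mean_encounters,
       mean_amplitude = res$mean_amplitude, amplitude = res$amplitude,
       n_legs = res$n_legs)
}

#' Deterministic fixtures for tests and examples
#'
#' * `"hand_bursts"`: a hand-written tracer log with reactions at steps
#'   100, 150, 2000, 2040, 2090 and 9000 (each dissociating 10 steps
#'   later); with tau_crit = 500 it segments into amplitudes 2, 3, 1 and
#'   gaps 1850 and 6910.
#' * `"tiny_sim"`: a seeded 2-particle simulation on a 12 x 12 lattice with
#'   4-site compartments (10^4 steps).
#' * `"free_walk"`: sampled displacement paths of 50 free walkers
#'   (p = 0.25).
#'
#' @param name Fixture name.
#' @return An `event_log` or `walker_paths` object, reproducibly identical
#'   across calls.
#' @export
make_fixture <- function(name) {
  switch(name,
    hand_bursts = {
      r <- c(100, 150, 2000, 2040, 2090, 9000)
      d <- r + 10
      steps <- c(rbind(r, d))
      ev <- tibble::tibble(step = steps,
                           event_type = rep(c("reaction", "dissociation"), length(r)),
                           partner_id = 1L, x = 0L, y = 0L,
                           comp_x = 0L, comp_y = 0L)
      cfg <- sim_config(lattice_spec(12, 4),
                        sim_params(0.01, n_particles = 2, n_steps = 1e4, seed = 1))
      structure(list(events = ev, config = cfg, n_steps = 1e4,
                     tracer_monomer_fraction = NA_real_), class = "event_log")
    },
    tiny_sim = simulate_reactions(
      sim_config(lattice_spec(12, 4),
                 sim_params(0.01, reaction_prob = 1, mean_dimer_lifetime = 50,
                            n_particles = 2, n_steps = 1e4, seed = 42))),
    free_walk = simulate_walkers(lattice_spec(40, 20), p = 0.25,
                                 n_walkers = 50, n_steps = 500, seed = 7),
    stop("unknown fixture: ", name, call. = FALSE))
}

#' Sampled single-walker escape times
#'
#' Stochastic counterpart of [exact_escape_pmf()]: walkers released
#' uniformly in one compartment of a 3 x 3-compartment torus, followed with
#' the full step rule until their compartment index changes.
#'
#' @inheritParams two_particle_burst_sim
#' @param reps Number of walkers.
#' @return Integer vector of escape times in steps.
#' @export
simulate_escape_times <- function(n, p, reps = 10000, seed = 1L) {
  stopifnot(n >= 2, p > 0, p <= 0.25)
  set.seed(seed)
  as.integer(engine_escape_samples(n, p, as.integer(reps)))
}
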
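#' Continuum permeability of the lattice barriers
#'
#' Maps the per-attempt barrier crossing probability p of the hop rule onto
#' the continuum boundary permeability P (length/time).  The closed form is
#' obtained by conductance homogenization of one barrier channel: with the
#' always-move rule, the stationary weight of a barrier-adjacent site is
#' reduced relative to interior sites and every non-barrier bond carries
#' conductance (1 - p)/3, which gives
#'
#' \deqn{P = \frac{a/\Delta t}{\tfrac{4(1-p)}{3p} + \tfrac{6}{1-p} - 12}.}
#'
#' P is zero for an impermeable barrier (p = 0), strictly increasing in p,
#' and diverges at p = 1/4 where the walk is exactly free.  For small p,
#' P ~ 3pa/(4 dt): the naive flux estimate p a/dt times the depleted
#' occupancy (3/4) of barrier-adjacent sites.
#'
#' @param p Crossing probability in \[0, 0.25\]; vectorized.
#' @param spacing,timestep Lattice constants a and dt.
#' @return Permeability in units of `spacing`/`timestep`.
#' @export
permeability_from_crossing <- function(p, spacing = 1, timestep = 1) {
  if (any(p < 0 | p > 0.25)) stop("`p` must lie in [0, 0.25]", call. = FALSE)
  out <- ifelse(p == 0, 0,
         ifelse(p == 0.25, Inf,
                (spacing / timestep) / (4 * (1 - p) / (3 * p) + 6 / (1 - p) - 12)))
  unname(out)
}

#' Confinement parameters of a compartmentalized membrane
#'
#' Bundles the quantities of the effective-diffusion theory: microscopic
#' diffusion coefficient D_micro = a^2/(4 dt), compartment length
#' l_c = n a, boundary permeability P, the dimensionless confinement
#' strength kappa = P l_c / D_micro (confinement is pronounced for
#' kappa << 1), and the long-time coefficient
#' D_macro = D_micro * kappa/(1 + kappa).
#'
#' @param compartment_sites Sites per compartment side (n >= 2).
#' @param crossing_prob Barrier crossing probability p; mapped to P via
#'   [permeability_from_crossing()].  Give exactly one of this,
#'   `permeability`, or `d_macro`.
#' @param permeability Boundary permeability P >= 0 directly.
#' @param d_macro Long-time diffusion coefficient; kappa and P are matched
#'   to it through D_macro = D_micro kappa/(1 + kappa).  Useful for feeding
#'   an exactly computed or simulated effective coefficient back into the
#'   escape-time theory.
#' @param spacing,timestep Lattice constants a and dt.
#' @return A `confinement_params` object.
#' @examples
#' cp <- confinement_params(20, crossing_prob = 0.005)
#' cp$kappa
#' diffusion_ratio(cp)
#' @export
confinement_params <- function(compartment_sites, crossing_prob = NULL,
                               permeability = NULL, d_macro = NULL,
                               spacing = 1, timestep = 1) {
  given <- !c(is.null(crossing_prob), is.null(permeability), is.null(d_macro))
  if (sum(given) != 1)
    stop("give exactly one of `crossing_prob`, `permeability` or `d_macro`", call. = FALSE)
  d_micro <- spacing^2 / (4 * timestep)
  ell_c <- compartment_sites * spacing
  if (!is.null(d_macro)) {
    if (d_macro < 0 || d_macro >= d_micro)
      stop("`d_macro` must lie in [0, D_micro)", call. = FALSE)
    kappa <- d_macro / (d_micro - d_macro)
    permeability <- kappa * d_micro / ell_c
  } else {
    if (is.null(permeability))
      permeability <- permeability_from_crossing(crossing_prob, spacing, timestep)
    if (permeability < 0) stop("`permeability` must be >= 0", call. = FALSE)
    kappa <- permeability * ell_c / d_micro
  }
  structure(list(d_micro = d_micro, ell_c = ell_c,
                 compartment_sites = as.integer(compartment_sites),
                 spacing = spacing, timestep = timestep,
                 permeability = permeability, kappa = kappa,
                 d_macro = if (is.infinite(kappa)) d_micro else d_micro * kappa / (1 + kappa)),
            class = "confinement_params")
}

#' @exportS3Method base::print
print.confinement_params <- function(x, ...) {
  cat(sprintf("<confinement_params> l_c=%g, D_micro=%g, P=%g, kappa=%g, D_macro=%g\n",
              x$ell_c, x$d_micro, x$permeability, x$kappa, x$d_macro))
  invisible(x)
}

#' Ratio of microscopic to effective long-time diffusion coefficient
#'
#' For diffusion through an array of square compartments with permeable
#' boundaries the hindrance ratio is \eqn{D_{micro}/D_{macro} = 1 + 1/\kappa}:
#' 1 in the free limit (kappa -> Inf) and divergent for impermeable barriers
#' (P = 0).
#'
#' @param params A [confinement_params()].
#' @return The dimensionless ratio (>= 1; `Inf` when P = 0).
#' @export
diffusion_ratio <- function(params) {
  stopifnot(inherits(params, "confinement_params"))
  if (params$kappa == 0) Inf else 1 + 1 / params$kappa
}

# 1D radiation-boundary eigenvalue problem on [0, l]:
# alpha * tan(alpha l / 2) = P / D, one root per branch.
escape_roots_1d <- function(ell, P, D, K, tol = 1e-10) {
  f <- function(al) al * tan(al * ell / 2) - P / D
  vapply(seq_len(K) - 1, function(k) {
    lo <- 2 * k * pi / ell + 1e-12
    hi <- (2 * k + 1) * pi / ell - 1e-12
    r <- stats::uniroot(f, c(lo, hi), tol = tol)
    if (abs(r$f.root) > 1e-4 * max(1, P / D))
      stop("root bracketing failed on branch ", k, call. = FALSE)
    r$root
  }, numeric(1))
}

#' Escape-time spectrum of a compartment with permeable walls
#'
#' Distribution of the first time a diffusing molecule leaves a square
#' compartment of side l_c with boundary permeability P, averaged over a
#' uniform initial position.  Separating the square problem into two
#' one-dimensional radiation-boundary problems, the survival probability is
#' \eqn{S(t) = \left[\sum_k A_k e^{-D\alpha_k^2 t}\right]^2} with the
#' \eqn{\alpha_k} the positive solutions of
#' \eqn{\alpha \tan(\alpha l_c/2) = P/D}; the escape-time density is a sum
#' of exponentials over the pair rates
#' \eqn{\lambda_{jk} = D(\alpha_j^2+\alpha_k^2)}.  Roots are found by
#' per-branch bracketing (one simple root between consecutive singularities
#' of the tangent), so no root can be skipped.
#'
#' @param params A [confinement_params()] with P > 0.
#' @param K Number of one-dimensional modes retained (the two-dimensional
#'   expansion then carries K^2 exponentials).
#' @return An `escape_spectrum` object: ascending `rates` (lambda), matching
#'   survival `weights` (summing to 1 within truncation error), the 1D
#'   modes, and the spectral mean escape time.
#' @seealso [escape_density()], [escape_survival()], [mean_escape_times()]
#' @export
escape_spectrum <- function(params, K = 50) {
  stopifnot(inherits(params, "confinement_params"), K >= 1)
  if (params$permeability <= 0)
    stop("escape spectrum requires P > 0 (impermeable walls never release the walker)", call. = FALSE)
  ell <- params$ell_c; D <- params$d_micro; P <- params$permeability
  al <- escape_roots_1d(ell, P, D, K)
  A <- (4 * sin(al * ell / 2)^2 / al^2) /
       (ell * (ell / 2 + sin(al * ell) / (2 * al)))
  lam1 <- D * al^2
  rates <- outer(lam1, lam1, `+`)
  weights <- outer(A, A)
  ord <- order(rates)
  structure(list(rates = as.vector(rates)[ord], weights = as.vector(weights)[ord],
                 modes_1d = tibble::tibble(alpha = al, rate = lam1, weight = A),
                 mean = sum(weights / rates), params = params, K = K),
            class = "escape_spectrum")
}

#' @exportS3Method base::print
print.escape_spectrum <- function(x, ...) {
  cat(sprintf("<escape_spectrum> K=%d modes/axis, mean escape %.4g, weight sum %.6f\n",
              x$K, x$mean, sum(x$weights)))
  invisible(x)
}

#' Escape-time density and survival function
#'
#' @param spectrum An [escape_spectrum()].
#' @param t Times (same units as the spectrum's parameters).
#' @return Numeric vector of densities / survival probabilities.
#' @export
escape_density <- function(spectrum, t) {
  vapply(t, function(tt) sum(spectrum$weights * spectrum$rates * exp(-spectrum$rates * tt)),
         numeric(1))
}

#' @rdname escape_density
#' @export
escape_survival <- function(spectrum, t) {
  vapply(t, function(tt) sum(spectrum$weights * exp(-spectrum$rates * tt)), numeric(1))
}

#' Mean compartment escape times for one molecule and for a pair
#'
#' The single-molecule mean escape time from a compartment of area l_c^2 is
#' approximated by the time to cover the compartment at the effective
#' long-time coefficient, \eqn{T_{esc} = l_c^2/(4 D_{macro})} (the
#' `"scaling"` method; exact in the strong-confinement limit), or computed
#' from the escape-time spectrum (`"spectral"`, accurate at moderate
#' confinement too).  With two molecules diffusing independently, the time
#' until either escapes is exactly half the single-molecule value under the
#' single-exponential approximation: `pair = single / 2`.
#'
#' @param params A [confinement_params()].
#' @param method `"scaling"` or `"spectral"`.
#' @param K Modes per axis for the spectral method.
#' @return List with elements `single` and `pair` (time units; `Inf` when
#'   D_macro = 0).
#' @export
mean_escape_times <- function(params, method = c("scaling", "spectral"), K = 50) {
  stopifnot(inherits(params, "confinement_params"))
  method <- match.arg(method)
  single <- if (params$d_macro == 0) Inf
            else if (method == "scaling") params$ell_c^2 / (4 * params$d_macro)
            else escape_spectrum(params, K)$mean
  list(single = single, pair = single / 2)
}

# Re-encounter scaling coefficient: T_reenc = coef * l_c^2 / (4 D_micro).
# Calibrated once by simulation at the reference geometry n = 20 (5e5
# dissociated pairs released uniformly, reflecting walls; SE 0.0015); the
# exact product-chain values for n = 3..6 (0.444, 0.441, 0.444, 0.449)
# approach the same plateau from below.
.reenc_coef <- 0.479

#' Mean re-encounter time of a freshly dissociated pair
#'
#' Average time for two molecules released on the same (uniformly chosen)
#' site of a compartment with reflecting walls to co-occupy a site again.
#' Reflecting walls realize the idealization that the pair cannot escape:
#' barrier-direction probability mass is redistributed over the allowed
#' directions, preserving the always-move dynamics.  The `"scaling"` method
#' returns coef * l_c^2/(4 D_micro) with a coefficient calibrated once
#' against simulation at n = 20 (and checked against exact product-chain
#' computations for n <= 6); `"simulated"` runs the two-walker chain itself;
#' `"exact"` solves the parity-restricted product chain (n <= 6).
#'
#' @param params A [confinement_params()].
#' @param method `"scaling"`, `"simulated"` or `"exact"`.
#' @param reps Pair releases for the simulated method.
#' @return Mean re-encounter time (time units), with the scaling coefficient
#'   as attribute `"coef"`.
#' @export
reencounter_time <- function(params, method = c("scaling", "simulated", "exact"),
                             reps = 50000) {
  stopifnot(inherits(params, "confinement_params"))
  method <- match.arg(method)
  n <- params$compartment_sites
  t <- switch(method,
    scaling = .reenc_coef * params$ell_c^2 / (4 * params$d_micro),
    simulated = engine_pair_reencounter(n, reps)$mean * params$timestep,
    exact = exact_pair_reencounter(n) * params$timestep)
  structure(t, coef = .reenc_coef)
}

#' Fugitive probability: escape before re-encounter
#'
#' Probability that a freshly dissociated pair separates into different
#' compartments before its members meet again, treating re-encounter (mean
#' `t_reencounter`) and pair escape (mean `t_escape_pair`) as competing
#' exponential clocks:
#' \deqn{P_{fug} = \frac{t_{re}}{t_{re} + T_{esc,2}}.}
#' Instant escape gives 1; impermeable walls give 0.
#'
#' @param t_reencounter Mean re-encounter time (> 0).
#' @param t_escape_pair Mean pair escape time (> 0; `Inf` allowed).
#' @return Probability in (0, 1\].
#' @export
fugitive_probability <- function(t_reencounter, t_escape_pair) {
  if (any(t_reencounter <= 0) || any(t_escape_pair <= 0))
    stop("both mean times must be positive", call. = FALSE)
  ifelse(is.infinite(t_escape_pair), 0, t_reencounter / (t_reencounter + t_escape_pair))
}

#' Burst amplitude distribution and mean number of encounters
#'
#' Within a burst, each dissociation is followed by a race: with probability
#' `p_fug` the pair separates before re-encountering (the burst ends), else
#' it re-encounters and reacts with probability `p_r`.  The probability that
#' another reaction occurs before escape is therefore
#' \eqn{q = (1-P_{fug})\,p_r / (1 - (1-P_{fug})(1-p_r))}, obtained by
#' summing over any number of unreactive encounters, and the number of
#' reactions in a burst (counting the initiating one) is geometric:
#' \eqn{\Pr(A = k) = q^{k-1}(1-q)},
#' \eqn{\langle A\rangle = \frac{1 - (1-P_{fug})(1-p_r)}{P_{fug}}.}
#' The number of encounters between consecutive escapes has mean
#' \eqn{\langle m\rangle = (1-P_{fug})/P_{fug}}; at p_r = 1 every encounter
#' reacts and \eqn{\langle A\rangle = \langle m\rangle + 1}.
#'
#' @param p_r Reaction probability per encounter, in (0, 1\].
#' @param p_fug Fugitive probability, in (0, 1\].
#' @return List with `mean_amplitude`, `mean_encounters`, the per-burst
#'   continuation probability `q`, and `pmf(k)`.
#' @export
burst_amplitude_stats <- function(p_r, p_fug) {
  if (p_r <= 0 || p_r > 1) stop("`p_r` must lie in (0, 1]", call. = FALSE)
  if (p_fug <= 0 || p_fug > 1) stop("`p_fug` must lie in (0, 1]", call. = FALSE)
  q <- (1 - p_fug) * p_r / (1 - (1 - p_fug) * (1 - p_r))
  list(mean_amplitude = (1 - (1 - p_fug) * (1 - p_r)) / p_fug,
       mean_encounters = (1 - p_fug) / p_fug,
       q = q,
       pmf = function(k) ifelse(k >= 1, q^(k - 1) * (1 - q), 0))
}

#' Full analytical pipeline for one parameter set
#'
#' Chains the theory layer end to end: permeability, confinement strength,
#' diffusion hindrance, mean escape times, re-encounter time, fugitive
#' probability, burst amplitude statistics and the rate-invariance constant,
#' for a single (p, n, p_r) combination.
#'
#' @param crossing_prob Barrier crossing probability p.
#' @param compartment_sites Compartment side n (sites).
#' @param reaction_prob Reaction probability per encounter p_r.
#' @param spacing,timestep Lattice constants.
#' @param escape_method Escape-mean method fed to the fugitive probability:
#'   `"spectral"` (default; accurate at moderate confinement) or
#'   `"scaling"` (the l_c^2/(4 D_macro) approximation).
#' @param reencounter_method Passed to [reencounter_time()].
#' @param K Spectral truncation.
#' @param reps Pair releases when `reencounter_method = "simulated"`.
#' @return One-row tibble with every derived quantity.
#' @examples
#' burst_theory(0.005, 20)
#' @export
burst_theory <- function(crossing_prob, compartment_sites, reaction_prob = 1,
                         spacing = 1, timestep = 1,
                         escape_method = c("spectral", "scaling"),
                         reencounter_method = c("scaling", "simulated", "exact"),
                         K = 50, reps = 50000) {
  escape_method <- match.arg(escape_method)
  cp <- confinement_params(compartment_sites, crossing_prob = crossing_prob,
                           spacing = spacing, timestep = timestep)
  esc <- mean_escape_times(cp, method = escape_method, K = K)
  tre <- reencounter_time(cp, method = match.arg(reencounter_method), reps = reps)
  pfug <- fugitive_probability(tre, esc$pair)
  bs <- burst_amplitude_stats(reaction_prob, pfug)
  tibble::tibble(
    crossing_prob = crossing_prob, compartment_sites = compartment_sites,
    reaction_prob = reaction_prob,
    permeability = cp$permeability, kappa = cp$kappa,
    d_micro = cp$d_micro, d_macro = cp$d_macro,
    diffusion_ratio = diffusion_ratio(cp),
    t_escape_single = esc$single, t_escape_pair = esc$pair,
    t_reencounter = as.numeric(tre),
    tau_crit = round(mean_escape_times(cp, "scaling")$pair / timestep),
    p_fug = pfug,
    mean_encounters = bs$mean_encounters, mean_amplitude = bs$mean_amplitude,
    invariance_constant = (cp$d_macro / cp$d_micro) * bs$mean_encounters)
}

#' Invariance of the mean reaction rate under confinement
#'
#' In the presence of compartments, encounters happen hierarchically: pairs
#' first find the same compartment (at a rate rescaled by
#' D_macro/D_micro), then meet repeatedly inside it (on average `m` times
#' before separating).  The confined rate is
#' \eqn{\Gamma_{conf} = (D_{macro}/D_{micro})\,\langle m\rangle\,\Gamma_{free}
#'  = c\,\Gamma_{free}}.
#' With \eqn{\langle m\rangle = T_{esc,2}/T_{re}}, the scaling forms
#' \eqn{T_{esc,2} = l_c^2/(8 D_{macro})} and
#' \eqn{T_{re} \propto l_c^2/(4 D_{micro})} make the D_macro and l_c factors
#' cancel exactly, so the constant c depends on neither the permeability nor
#' the compartment size -- the reason the asymptotic single-molecule
#' reaction rate does not depend on confinement strength.
#'
#' @param rate_free Mean reaction rate in the absence of barriers (1/time).
#' @param params A [confinement_params()].
#' @param escape_method `"spectral"` or `"scaling"` for the pair escape mean
#'   entering `m` (the `"scaling"` choice gives an exactly constant c).
#' @param K Spectral truncation.
#' @return List with `rate_confined`, `invariance_constant` and
#'   `mean_encounters`.
#' @export
rate_invariance <- function(rate_free, params,
                            escape_method = c("scaling", "spectral"), K = 50) {
  stopifnot(inherits(params, "confinement_params"))
  esc <- mean_escape_times(params, method = match.arg(escape_method), K = K)
  tre <- reencounter_time(params, "scaling")
  m <- esc$pair / as.numeric(tre)
  cc <- (params$d_macro / params$d_micro) * m
  list(rate_confined = cc * rate_free, invariance_constant = cc,
       mean_encounters = m)
}

#' Equilibrium monomer fraction of the reversible dimerization
#'
#' For N molecules undergoing M + M <-> D with monomer energy e_M and dimer
#' energy e_D (pair interactions neglected), the canonical partition
#' function sums over the number of dimer pairs j with multiplicity
#' N! / ((N - 2j)! j! 2^j).  The equilibrium monomer fraction follows either
#' by exact enumeration of that sum (`method = "exact"`) or from its
#' large-N saddle point, which solves \eqn{N\phi^2 = K(1-\phi)} with
#' \eqn{K = e^{\beta(\epsilon_D - 2\epsilon_M)}}:
#' \deqn{\phi = \frac{-K + \sqrt{K^2 + 4NK}}{2N}.}
#' The fraction tends to 0 when the dimer state is strongly favorable and
#' to 1 when the monomer state is.
#'
#' @param n_particles N (even for the exact sum).
#' @param energy_monomer,energy_dimer Energies e_M (per monomer) and e_D
#'   (per dimer), in units of 1/`beta`.
#' @param beta Inverse temperature 1/(k_B T).
#' @param method `"closed_form"` (large-N) or `"exact"` (finite-N sum).
#' @return Monomer fraction in \[0, 1\].
#' @examples
#' monomer_fraction(20, 0, -2)                    # dimer favorable
#' monomer_fraction(4, 0, 0, method = "exact")
#' @export
monomer_fraction <- function(n_particles, energy_monomer = 0, energy_dimer = 0,
                             beta = 1, method = c("closed_form", "exact")) {
  stopifnot(n_particles >= 2)
  K <- exp(beta * (energy_dimer - 2 * energy_monomer))
  N <- n_particles
  if (match.arg(method) == "closed_form")
    return(min(1, max(0, (-K + sqrt(K^2 + 4 * N * K)) / (2 * N))))
  if (N %% 2 != 0) stop("the exact partition sum requires even N", call. = FALSE)
  j <- 0:(N %/% 2)
  logterm <- lfactorial(N) - lfactorial(N - 2 * j) - lfactorial(j) -
    j * log(2) - j * log(K)
  w <- exp(logterm - max(logterm))
  sum((N - 2 * j) * w) / (N * sum(w))
}

#' Map lattice units onto physical membrane units
#'
#' Given the physical compartment size and the microscopic (within-
#' compartment) diffusion coefficient, returns the lattice spacing and time
#' step: a = compartment size / n, and dt = a^2/(4 D_micro) so that the
#' always-move lattice walk reproduces D_micro.
#'
#' @param compartment_nm Compartment side length in nanometers.
#' @param d_micro_um2_s Microscopic diffusion coefficient in micrometer^2/s.
#' @param compartment_sites Lattice sites per compartment side (n).
#' @return Tibble with `spacing_nm` and `timestep_s`.
#' @examples
#' physical_units(40, 8, 20)   # 2 nm spacing, 1.25e-7 s per step
#' @export
physical_units <- function(compartment_nm, d_micro_um2_s, compartment_sites) {
  stopifnot(compartment_nm > 0, d_micro_um2_s > 0, compartment_sites >= 2)
  a_nm <- compartment_nm / compartment_sites
  dt_s <- a_nm^2 / (4 * d_micro_um2_s * 1e6)   # 1 um^2 = 1e6 nm^2
  tibble::tibble(spacing_nm = a_nm, timestep_s = dt_s)
}
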
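#' Waiting times between successive tracer reactions
#'
#' Under the `"dissociation_to_reaction"` convention each waiting time runs
#' from a dissociation to the next reaction (the search time, decoupled from
#' the dimer dwell); under `"reaction_to_reaction"` it is the difference of
#' consecutive reaction steps (search time plus dwell).
#'
#' @param log An `event_log` from [simulate_reactions()] (or its `events`
#'   tibble).
#' @param convention Waiting-time convention; defaults to the one in the
#'   log's configuration.
#' @return Tibble with `wait` (steps), `from_step`, `to_step`; the
#'   convention is kept as attribute `"convention"`.  Fewer than two
#'   reactions give an empty series.
#' @export
inter_reaction_times <- function(log, convention = NULL) {
  ev <- events_of(log)
  if (is.null(convention)) convention <- log_convention(log)
  convention <- match.arg(convention,
                          c("dissociation_to_reaction", "reaction_to_reaction"))
  r <- ev$step[ev$event_type == "reaction"]
  d <- ev$step[ev$event_type == "dissociation"]
  out <- if (length(r) < 2) {
    tibble::tibble(wait = numeric(0), from_step = numeric(0), to_step = numeric(0))
  } else if (convention == "reaction_to_reaction") {
    tibble::tibble(wait = diff(r), from_step = r[-length(r)], to_step = r[-1])
  } else {
    k <- seq_len(length(r) - 1)       # dissociation k precedes reaction k+1
    tibble::tibble(wait = r[k + 1] - d[k], from_step = d[k], to_step = r[k + 1])
  }
  attr(out, "convention") <- convention
  out
}

events_of <- function(log) {
  if (inherits(log, "event_log")) log$events
  else { stopifnot(is.data.frame(log)); log }
}

log_convention <- function(log) {
  if (inherits(log, "event_log")) log$config$params$inter_reaction_convention
  else "dissociation_to_reaction"
}

wait_vector <- function(x) {
  if (is.numeric(x)) x
  else if (is.data.frame(x) && "wait" %in% names(x)) x$wait
  else if (inherits(x, "event_log")) inter_reaction_times(x)$wait
  else stop("cannot interpret input as a waiting-time series", call. = FALSE)
}

#' Default burst-segmentation threshold
#'
#' The natural timescale separating within-burst re-encounters from
#' between-burst excursions is the time for one of the two partners to
#' leave the compartment: tau_crit defaults to the pair mean escape time
#' (half the single-molecule l_c^2/(4 D_macro) scaling form), rounded to
#' whole steps.  A `tau_crit` stored in the configuration overrides it.
#'
#' @param config A [sim_config()].
#' @return Threshold in steps.
#' @export
default_tau_crit <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$tau_crit)) return(config$tau_crit)
  cp <- confinement_params(config$spec$compartment_sites,
                           crossing_prob = config$params$crossing_prob,
                           spacing = config$spec$spacing,
                           timestep = config$spec$timestep)
  max(1, round(mean_escape_times(cp, "scaling")$pair / config$spec$timestep))
}

#' Segment the tracer reaction record into bursts and gaps
#'
#' A burst is a maximal run of consecutive reactions whose successive
#' waiting times do not exceed `tau_crit`; isolated reactions count as
#' bursts of amplitude 1.  Gaps run from the last reaction of one burst to
#' the first reaction of the next.  The first and last burst of a record
#' are censored (the record may have cut them short); they are flagged and
#' retained in amplitude statistics, while gap statistics are unaffected
#' because gaps only exist between observed bursts.
#'
#' @param log An `event_log` (or events tibble).
#' @param tau_crit Threshold in steps; defaults to [default_tau_crit()] of
#'   the log's configuration.
#' @param convention Waiting-time convention for the threshold comparison;
#'   defaults to the configuration's.
#' @return A `burst_partition`: tibbles `bursts` (`first_step`, `last_step`,
#'   `amplitude`, `censored`) and `gaps` (`duration`), the waiting-time
#'   table, `tau_crit` and the convention.
#' @examples
#' log <- make_fixture("hand_bursts")
#' segment_bursts(log, tau_crit = 500)
#' @export
segment_bursts <- function(log, tau_crit = NULL, convention = NULL) {
  ev <- events_of(log)
  if (is.null(tau_crit)) {
    if (!inherits(log, "event_log"))
      stop("`tau_crit` must be given when no configuration is attached", call. = FALSE)
    tau_crit <- default_tau_crit(log$config)
  }
  irt <- inter_reaction_times(log, convention)
  r <- ev$step[ev$event_type == "reaction"]
  d <- ev$step[ev$event_type == "dissociation"]
  if (length(r) == 0) {
    return(structure(list(bursts = tibble::tibble(first_step = numeric(0),
                                                  last_step = numeric(0),
                                                  amplitude = integer(0),
                                                  censored = logical(0)),
                          gaps = tibble::tibble(duration = numeric(0)),
                          waits = irt, tau_crit = tau_crit,
                          convention = attr(irt, "convention")),
                     class = "burst_partition"))
  }
  brk <- which(irt$wait > tau_crit)            # burst ends after reaction brk
  first_idx <- c(1, brk + 1)
  last_idx <- c(brk, length(r))
  bursts <- tibble::tibble(
    first_step = r[first_idx], last_step = r[last_idx],
    amplitude = as.integer(last_idx - first_idx + 1L),
    censored = seq_along(first_idx) %in% c(1L, length(first_idx)))
  gaps <- tibble::tibble(duration = if (nrow(bursts) > 1)
    bursts$first_step[-1] - bursts$last_step[-nrow(bursts)] else numeric(0))
  structure(list(bursts = bursts, gaps = gaps, waits = irt,
                 tau_crit = tau_crit, convention = attr(irt, "convention")),
            class = "burst_partition")
}

#' @exportS3Method base::print
print.burst_partition <- function(x, ...) {
  cat(sprintf("<burst_partition> %d bursts (tau_crit = %g, %s), %d gaps\n",
              nrow(x$bursts), x$tau_crit, x$convention, nrow(x$gaps)))
  if (nrow(x$bursts) > 0)
    cat(sprintf("  mean amplitude %.3g, mean gap %.4g steps\n",
                mean(x$bursts$amplitude),
                if (nrow(x$gaps)) mean(x$gaps$duration) else NA))
  invisible(x)
}

#' Summary statistics of a burst partition
#'
#' Arithmetic mean gap duration and burst amplitude with percentile
#' bootstrap confidence intervals.
#'
#' @param partition A [segment_bursts()] result with at least one burst.
#' @param n_boot,level Bootstrap replicates and confidence level.
#' @param seed Seed for the bootstrap resampling.
#' @return One-row tibble: burst and gap counts, means, and CI bounds
#'   (`NA` and `gap_defined = FALSE` when there are no gaps).
#' @export
summarize_bursts <- function(partition, n_boot = 1000, level = 0.95, seed = 1L) {
  stopifnot(inherits(partition, "burst_partition"), nrow(partition$bursts) >= 1)
  amp <- partition$bursts$amplitude
  aci <- if (length(amp) >= 2) bootstrap_ci(amp, mean, n_boot, level, seed = seed)
         else c(amp, amp)
  g <- partition$gaps$duration
  gci <- if (length(g) >= 2) bootstrap_ci(g, mean, n_boot, level, seed = seed + 1L)
         else if (length(g) == 1) c(g, g)
         else c(NA_real_, NA_real_)
  tibble::tibble(n_bursts = length(amp), mean_amplitude = mean(amp),
                 amplitude_lo = aci[1], amplitude_hi = aci[2],
                 n_gaps = length(g), gap_defined = length(g) > 0,
                 mean_gap = if (length(g)) mean(g) else NA_real_,
                 gap_lo = gci[1], gap_hi = gci[2],
                 tau_crit = partition$tau_crit)
}

#' Confined-to-free waiting time ratios
#'
#' R_mean and R_std compare the mean and standard deviation of the
#' inter-reaction waiting time in a compartmentalized system to a
#' barrier-free reference.  Asymptotically the mean is insensitive to
#' confinement (R_mean ~ 1) while the standard deviation grows with
#' confinement strength -- the signature of reaction bursts.
#'
#' @param confined,free Waiting-time series (numeric vectors, tibbles from
#'   [inter_reaction_times()], or event logs).
#' @param n_boot,level,seed Bootstrap settings (independent resampling of
#'   the two series in each replicate).
#' @return One-row tibble with `r_mean`, `r_std` and their CI bounds.
#' @export
ratio_stats <- function(confined, free, n_boot = 1000, level = 0.95, seed = 1L) {
  wc <- wait_vector(confined); wf <- wait_vector(free)
  if (length(wc) < 2 || length(wf) < 2)
    stop("both series need at least two waiting times", call. = FALSE)
  if (stats::sd(wf) == 0)
    stop("free series has zero variance; R_std undefined", call. = FALSE)
  r_mean <- mean(wc) / mean(wf)
  r_std <- stats::sd(wc) / stats::sd(wf)
  old <- .Random.seed_save(seed)
  on.exit(.Random.seed_restore(old))
  reps <- vapply(seq_len(n_boot), function(i) {
    bc <- wc[sample.int(length(wc), replace = TRUE)]
    bf <- wf[sample.int(length(wf), replace = TRUE)]
    c(mean(bc) / mean(bf),
      if (stats::sd(bf) > 0) stats::sd(bc) / stats::sd(bf) else NA_real_)
  }, numeric(2))
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qm <- stats::quantile(reps[1, ], qs, na.rm = TRUE)
  qsd <- stats::quantile(reps[2, ], qs, na.rm = TRUE)
  tibble::tibble(r_mean = r_mean, r_mean_lo = qm[[1]], r_mean_hi = qm[[2]],
                 r_std = r_std, r_std_lo = qsd[[1]], r_std_hi = qsd[[2]],
                 n_confined = length(wc), n_free = length(wf))
}

.Random.seed_save <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  if (!is.null(seed)) set.seed(seed)
  old
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Percentile bootstrap confidence interval
#'
#' @param x Numeric series (length >= 2).
#' @param statistic Function of a numeric vector.
#' @param n_boot Number of resamples.
#' @param level Confidence level.
#' @param seed Optional seed (the caller's RNG state is restored).
#' @return `c(lower, upper)` with the plug-in estimate as attribute
#'   `"estimate"`.  A constant series gives a zero-width interval flagged
#'   with attribute `"degenerate"`.
#' @export
bootstrap_ci <- function(x, statistic = mean, n_boot = 1000, level = 0.95,
                         seed = NULL) {
  stopifnot(length(x) >= 2, n_boot >= 1, level > 0, level < 1)
  est <- statistic(x)
  if (length(unique(x)) == 1L)
    return(structure(c(est, est), estimate = est, degenerate = TRUE))
  old <- .Random.seed_save(seed)
  on.exit(.Random.seed_restore(old))
  reps <- vapply(seq_len(n_boot),
                 function(i) statistic(x[sample.int(length(x), replace = TRUE)]),
                 numeric(1))
  ci <- unname(stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2)))
  structure(ci, estimate = est, degenerate = FALSE)
}

#' Per-compartment local reaction rate series
#'
#' The quantity animated in the simulation visualizations: for each
#' compartment, `scale` times the number of reactions that took place there
#' during the trailing `window` steps.
#'
#' @param log An `event_log` recorded with `record = "all"`.
#' @param window Trailing window length in steps (> 0).
#' @param scale Multiplier applied to the window count.
#' @param at_steps Steps at which to evaluate the series; defaults to a
#'   grid every `window` steps.
#' @return Tibble with `step`, `comp_x`, `comp_y`, `rate` covering every
#'   compartment of the lattice.
#' @export
local_rate_series <- function(log, window = 100, scale = 10, at_steps = NULL) {
  stopifnot(inherits(log, "event_log"))
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  if (is.null(log$all_events))
    stop("log must be recorded with record = \"all\"", call. = FALSE)
  if (is.null(at_steps)) at_steps <- seq(window, log$n_steps, by = window)
  m <- log$config$spec$compartments_per_side
  grid <- tidyr::expand_grid(comp_x = 0:(m - 1), comp_y = 0:(m - 1))
  ev <- log$all_events
  out <- purrr::pmap_dfr(grid, function(comp_x, comp_y) {
    s <- sort(ev$step[ev$comp_x == comp_x & ev$comp_y == comp_y])
    cnt <- findInterval(at_steps, s) - findInterval(at_steps - window, s)
    tibble::tibble(step = at_steps, comp_x = comp_x, comp_y = comp_y,
                   rate = scale * cnt)
  })
  dplyr::arrange(out, .data$step, .data$comp_x, .data$comp_y)
}

#' Ensemble-averaged cumulative reaction count
#'
#' Splits the run into `n_segments` equal non-overlapping spans and averages
#' the cumulative tracer reaction count as a function of time within the
#' segment.  For a stationary event stream the averaged curve is a straight
#' line with slope equal to the mean reaction rate, whatever the burst
#' structure.
#'
#' @param log An `event_log` (or events tibble plus `n_steps`).
#' @param n_segments Number of segments.
#' @param n_steps Total steps (taken from the log when omitted).
#' @return Tibble with `offset` (steps into the segment) and `mean_count`,
#'   with attribute `"low_power"` set when fewer events than segments were
#'   available.
#' @export
ensemble_reaction_count <- function(log, n_segments = 1000, n_steps = NULL) {
  ev <- events_of(log)
  if (is.null(n_steps)) {
    stopifnot(inherits(log, "event_log"))
    n_steps <- log$n_steps
  }
  seg <- floor(n_steps / n_segments)
  if (seg < 1) stop("more segments than steps", call. = FALSE)
  r <- ev$step[ev$event_type == "reaction"]
  r <- r[r <= seg * n_segments]
  offs <- ((r - 1) %% seg) + 1
  counts <- tabulate(offs, nbins = seg)
  out <- tibble::tibble(offset = seq_len(seg),
                        mean_count = cumsum(counts) / n_segments)
  attr(out, "low_power") <- length(r) < n_segments
  out
}

#' Normalized histogram of waiting times
#'
#' @param series Waiting-time series (vector, tibble, or event log).
#' @param bin_width Bin width in steps (> 0).
#' @return Tibble with `bin_left`, `bin_right`, `count`, `prob`
#'   (probabilities sum to 1).
#' @export
waiting_time_histogram <- function(series, bin_width = 100) {
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  w <- wait_vector(series)
  if (length(w) == 0) stop("empty waiting-time series", call. = FALSE)
  bin <- floor(w / bin_width)
  tab <- table(bin)
  lefts <- as.numeric(names(tab)) * bin_width
  tibble::tibble(bin_left = lefts, bin_right = lefts + bin_width,
                 count = as.integer(tab), prob = as.integer(tab) / length(w))
}

#' Per-segment tracer monomer fraction
#'
#' Splits the run into equal segments and returns the fraction of steps the
#' tracer spent as a monomer in each, reconstructed from the reaction/
#' dissociation intervals of the event log.  Segment fractions feed
#' [bootstrap_ci()] to put a confidence interval on the long-run monomer
#' fraction of a single run.
#'
#' @param log An `event_log`.
#' @param n_segments Number of equal segments.
#' @return Tibble with `segment` and `fraction`.
#' @export
monomer_fraction_series <- function(log, n_segments = 20) {
  stopifnot(inherits(log, "event_log"), n_segments >= 1)
  ev <- events_of(log)
  r <- ev$step[ev$event_type == "reaction"]
  d <- ev$step[ev$event_type == "dissociation"]
  if (length(d) < length(r)) d <- c(d, log$n_steps)   # still dimerized at the end
  seg <- log$n_steps / n_segments
  bounds <- seg * (0:n_segments)
  dimer_occ <- vapply(seq_len(n_segments), function(k) {
    a <- bounds[k]; b <- bounds[k + 1]
    sum(pmax(0, pmin(d, b) - pmax(r, a)))
  }, numeric(1))
  tibble::tibble(segment = seq_len(n_segments), fraction = 1 - dimer_occ / seg)
}
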
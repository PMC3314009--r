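run_cfg <- function(p, n_steps = 1e4, seed = 1, N = 10, p_r = 1, taud = 100,
                    L = 60, n = 20, ...) {
  sim_config(lattice_spec(L, n),
             sim_params(p, reaction_prob = p_r, mean_dimer_lifetime = taud,
                        n_particles = N, n_steps = n_steps, seed = seed, ...))
}

test_that("identical seed and configuration give bit-identical event logs", {
  cfg <- run_cfg(0.05, n_steps = 5e4, seed = 33)
  a <- simulate_reactions(cfg)
  b <- simulate_reactions(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$tracer_monomer_fraction, b$tracer_monomer_fraction)
  d <- simulate_reactions(run_cfg(0.05, n_steps = 5e4, seed = 34))
  expect_false(identical(a$events, d$events))
})

test_that("tracer reaction and dissociation events strictly alternate", {
  log <- simulate_reactions(run_cfg(0.25, n_steps = 2e5, seed = 2))
  ev <- log$events
  expect_gt(nrow(ev), 10)
  expect_identical(ev$event_type,
                   rep(c("reaction", "dissociation"), length.out = nrow(ev)))
  expect_true(all(diff(ev$step) >= 0))
  # a dimer lives at least one step
  r <- ev$step[ev$event_type == "reaction"]
  d <- ev$step[ev$event_type == "dissociation"]
  expect_true(all(d - r[seq_along(d)] >= 1))
})

test_that("degenerate configurations behave as contracted", {
  # a single particle has no partner: empty log forever
  log1 <- simulate_reactions(run_cfg(0.25, n_steps = 5e4, N = 1))
  expect_equal(nrow(log1$events), 0)
  expect_equal(log1$tracer_monomer_fraction, 1)
  # placement capacity: more particles than every-second-site slots
  expect_error(simulate_reactions(run_cfg(0.25, N = 33, L = 8, n = 4)),
               "cannot place")
})

test_that("two particles placed one empty site apart can react at step one", {
  # with N = 2 and p_r = 1 the pair starts two sites apart; the earliest
  # co-occupancy is the middle site after one step (prob 1/16 per run)
  firsts <- vapply(1:40, function(s) {
    ev <- simulate_reactions(run_cfg(0.25, n_steps = 5, seed = s, N = 2))$events
    if (nrow(ev)) ev$step[1] else Inf
  }, numeric(1))
  expect_true(any(firsts == 1))
  expect_true(all(firsts >= 1))
  # the only available partner is particle 1
  ev <- simulate_reactions(run_cfg(0.25, n_steps = 2e4, seed = 5, N = 2))$events
  expect_true(all(ev$partner_id == 1L))
})

test_that("dimer lifetimes are ceiling-rounded exponentials", {
  set.seed(7)
  lt <- sample_dimer_lifetime(2e5, 100)
  expect_true(all(lt >= 1))
  # analytic mean of ceil(Exp(100)): 1/(1 - exp(-1/100)) = 100.5008...
  expect_equal(dimer_lifetime_mean(100), 100.50083, tolerance = 1e-6)
  expect_equal(mean(lt), dimer_lifetime_mean(100), tolerance = 0.01)
  # empirical dwell of simulated dimers matches the same mean
  log <- simulate_reactions(run_cfg(0.25, n_steps = 1e6, seed = 11, L = 100))
  ev <- log$events
  dwell <- ev$step[ev$event_type == "dissociation"] -
    ev$step[ev$event_type == "reaction"][seq_len(sum(ev$event_type == "dissociation"))]
  expect_gt(length(dwell), 200)
  expect_equal(mean(dwell), dimer_lifetime_mean(100),
               tolerance = 3 * sd(dwell) / sqrt(length(dwell)) / 100)
})

test_that("simulated escape times match the exact absorbing chain", {
  es <- simulate_escape_times(4, 0.05, reps = 20000, seed = 9)
  ex <- exact_escape_pmf(4, 0.05, max_steps = max(es))
  expect_equal(mean(es), ex$mean, tolerance = 3 * sd(es) / sqrt(length(es)) / ex$mean)
  # sup distance between empirical and exact cdf (pure Monte Carlo error)
  cdf_exact <- cumsum(ex$pmf$prob)
  cdf_emp <- ecdf(es)(ex$pmf$step)
  expect_lt(max(abs(cdf_emp - cdf_exact)), 0.02)
})

test_that("at p = 0.25 displacements are indistinguishable from the free walk", {
  wp <- simulate_walkers(lattice_spec(200, 20), 0.25, n_walkers = 4000,
                         n_steps = 50, thin = 50, seed = 13)
  dx_sim <- wp$x[2, ] - wp$x[1, ]
  set.seed(14)   # reference: 50 steps, x chosen w.p. 1/2, then +/-1 equally
  sx <- stats::rbinom(4000, 50, 0.5)
  dx_ref <- 2 * stats::rbinom(4000, sx, 0.5) - sx
  pooled <- table(cut(c(dx_sim, dx_ref), breaks = c(-Inf, seq(-10, 10, by = 4), Inf)),
                  rep(c("sim", "ref"), each = 4000))
  expect_gt(stats::chisq.test(pooled)$p.value, 0.001)
})

test_that("free-walk MSD is exactly linear; confinement bends it down", {
  wp <- simulate_walkers(lattice_spec(40, 20), 0.25, n_walkers = 500,
                         n_steps = 2000, thin = 1, seed = 4)
  msd <- estimate_msd(wp, c(1, 2, 5, 10, 20, 50))
  expect_equal(msd$msd[1], 1)                      # the walker always moves
  expect_equal(msd$msd / msd$lag, rep(1, 6), tolerance = 0.03)
  # strong confinement: long-lag slope falls well below short-lag slope
  wps <- simulate_walkers(lattice_spec(40, 20), 0.001, n_walkers = 150,
                          n_steps = 3e4, thin = 10, seed = 6)
  m <- estimate_msd(wps, c(10, 10000))
  expect_lt(m$msd[2] / 10000, m$msd[1] / 10)
  expect_error(estimate_msd(wps, 30010), "exceeds")
  expect_error(estimate_msd(wps, 15), "multiples")
})

test_that("equilibrium monomer fraction does not depend on confinement strength", {
  # same density, reaction probability and lifetime; only p differs
  f <- vapply(c(0.25, 0.01), function(p) {
    simulate_reactions(run_cfg(p, n_steps = 2e6, seed = 21, L = 200)
    )$tracer_monomer_fraction
  }, numeric(1))
  expect_equal(f[1], f[2], tolerance = 0.02)
})
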
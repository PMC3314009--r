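test_that("permeability mapping has the right limits and monotonicity", {
  expect_equal(permeability_from_crossing(0), 0)
  expect_identical(permeability_from_crossing(0.25), Inf)
  grid <- seq(0.001, 0.249, length.out = 60)
  expect_true(all(diff(permeability_from_crossing(grid)) > 0))
  expect_error(permeability_from_crossing(0.3), "0.25")
  # weak-barrier flux limit: P -> 3 p a / (4 dt) as p -> 0
  expect_equal(permeability_from_crossing(1e-5), 3 * 1e-5 / 4, tolerance = 1e-3)
})

test_that("diffusion hindrance ratio: limits and exact-lattice accuracy", {
  free <- confinement_params(20, crossing_prob = 0.25)
  expect_equal(diffusion_ratio(free), 1)
  expect_equal(free$d_macro, free$d_micro)
  blocked <- confinement_params(20, permeability = 0)
  expect_identical(diffusion_ratio(blocked), Inf)
  expect_equal(blocked$d_macro, 0)
  # closed form vs the exact homogenization oracle
  for (p in c(0.05, 0.005)) {
    cp <- confinement_params(20, crossing_prob = p)
    exact_ratio <- cp$d_micro / exact_effective_diffusion(20, p)
    expect_equal(diffusion_ratio(cp), exact_ratio, tolerance = 0.02)
  }
  expect_equal(diffusion_ratio(confinement_params(40, crossing_prob = 0.005)),
               0.25 / exact_effective_diffusion(40, 0.005), tolerance = 0.012)
})

test_that("escape spectrum: normalization, ordering, and the exact-chain gate", {
  cp <- confinement_params(10, crossing_prob = 0.01)
  sp <- escape_spectrum(cp, K = 50)
  expect_equal(sum(sp$weights), 1, tolerance = 1e-6)
  expect_true(all(sp$rates > 0))
  expect_true(all(diff(sp$rates) >= 0))
  # density integrates to 1 (sum of weights) and is nonnegative on a grid
  tt <- seq(0.5, 8 * sp$mean, length.out = 100)
  expect_true(all(escape_density(sp, tt) >= 0))
  # spectral mean vs absorbing-chain exact mean
  ex <- exact_escape_pmf(10, 0.01)
  expect_equal(sp$mean, ex$mean, tolerance = 0.02)
  expect_error(escape_spectrum(confinement_params(10, permeability = 0)), "P > 0")
})

test_that("strong confinement collapses the escape density to one exponential", {
  cp <- confinement_params(10, permeability = 0.01 / 40)  # kappa = 0.01
  expect_equal(cp$kappa, 0.01)
  sp <- escape_spectrum(cp, K = 50)
  tt <- seq(0.1, 5, length.out = 150) * sp$mean
  f <- escape_density(sp, tt)
  fexp <- exp(-tt / sp$mean) / sp$mean
  expect_lt(max(abs(f - fexp) / fexp), 0.01)
})

test_that("mean escape times: pair is half of single; scaling limits", {
  cp <- confinement_params(20, crossing_prob = 0.005)
  et <- mean_escape_times(cp, "scaling")
  expect_equal(et$pair, et$single / 2)
  ets <- mean_escape_times(cp, "spectral")
  expect_equal(ets$pair, ets$single / 2)
  # halved D_macro doubles the escape time at fixed geometry
  half <- confinement_params(20, d_macro = cp$d_macro / 2)
  expect_equal(mean_escape_times(half, "scaling")$single, 2 * et$single)
  # impermeable walls: infinite escape time, flagged not thrown
  expect_identical(mean_escape_times(confinement_params(20, permeability = 0))$single, Inf)
  # 2x2 compartment: escape is geometric with mean 1/(2p); the scaling form
  # with kappa matched to the exact effective coefficient agrees within 10%
  cp2 <- confinement_params(2, d_macro = exact_effective_diffusion(2, 0.01))
  expect_equal(mean_escape_times(cp2, "scaling")$single, 1 / (2 * 0.01),
               tolerance = 0.10)
})

test_that("default tau_crit tracks the pair escape time", {
  cfg_free <- sim_config(lattice_spec(200, 20), sim_params(0.25))
  expect_equal(default_tau_crit(cfg_free), 200)  # free pair traversal scale n^2/2
  # halving p approximately doubles tau_crit (exactly, deep in kappa << 1)
  tc <- vapply(c(0.002, 0.001), function(p)
    default_tau_crit(sim_config(lattice_spec(200, 20), sim_params(p))), numeric(1))
  expect_gt(tc[2] / tc[1], 1.8)
  expect_lt(tc[2] / tc[1], 2.1)
  cfg_over <- sim_config(lattice_spec(200, 20), sim_params(0.25), tau_crit = 123)
  expect_equal(default_tau_crit(cfg_over), 123)
})

test_that("fugitive probability is the competing-clocks ratio", {
  expect_equal(fugitive_probability(100, 1e-9), 1, tolerance = 1e-6)
  expect_equal(fugitive_probability(100, Inf), 0)
  expect_equal(fugitive_probability(50, 150), 0.25)
  expect_error(fugitive_probability(-1, 10), "positive")
  expect_error(fugitive_probability(10, 0), "positive")
})

test_that("burst amplitude distribution: limits, monotonicity, consistency", {
  near1 <- burst_amplitude_stats(1, 0.9999)
  expect_equal(near1$mean_amplitude, 1, tolerance = 1e-3)
  amps <- vapply(c(0.1, 0.3, 0.6, 1), function(pr)
    burst_amplitude_stats(pr, 0.1)$mean_amplitude, numeric(1))
  expect_true(all(diff(amps) > 0))
  bs <- burst_amplitude_stats(0.7, 0.2)
  k <- 1:4000
  expect_equal(sum(bs$pmf(k)), 1, tolerance = 1e-10)
  expect_equal(sum(k * bs$pmf(k)), bs$mean_amplitude, tolerance = 1e-8)
  # p_r = 1: every encounter reacts, amplitude = encounters + 1
  b1 <- burst_amplitude_stats(1, 0.2)
  expect_equal(b1$mean_amplitude, b1$mean_encounters + 1)
})

test_that("theory fugitive probability and amplitude match brute force", {
  # exact re-encounter and exact escape means in the competing-clock formula
  tre <- exact_pair_reencounter(4)
  tesc2 <- exact_escape_pmf(4, 0.01)$mean / 2
  pf <- fugitive_probability(tre, tesc2)
  sim <- two_particle_burst_sim(4, 0.01, p_r = 1, tau_d = 50, reps = 20000, seed = 2)
  expect_equal(pf, sim$p_fug, tolerance = 0.10)
  # full pipeline amplitude (spectral escape mean) within 15%
  bt <- burst_theory(0.005, 4, reaction_prob = 1, reencounter_method = "exact")
  sim2 <- two_particle_burst_sim(4, 0.005, p_r = 1, tau_d = 50, reps = 20000, seed = 3)
  expect_equal(bt$mean_amplitude, sim2$mean_amplitude, tolerance = 0.15)
})

test_that("the rate-invariance constant does not depend on p or on n", {
  cs <- vapply(c(0.01, 0.005, 0.002), function(p)
    rate_invariance(1, confinement_params(20, crossing_prob = p))$invariance_constant,
    numeric(1))
  expect_equal(max(cs) - min(cs), 0, tolerance = 1e-12)
  c40 <- rate_invariance(1, confinement_params(40, crossing_prob = 0.005))$invariance_constant
  expect_equal(c40, cs[1], tolerance = 1e-12)
  # the constant is near one: confinement rescales search and burst factors
  # into near-exact compensation, hence R_mean ~ 1
  expect_gt(cs[1], 0.8); expect_lt(cs[1], 1.3)
  # mean encounters grow as barriers tighten while D_macro/D_micro shrinks
  m <- vapply(c(0.01, 0.002), function(p)
    rate_invariance(1, confinement_params(20, crossing_prob = p))$mean_encounters,
    numeric(1))
  expect_gt(m[2], m[1])
})

test_that("equilibrium monomer fraction: limits and finite-N agreement", {
  expect_lt(monomer_fraction(20, 0, -30), 1e-4)   # dimer strongly favorable
  expect_gt(monomer_fraction(20, 0, 30), 1 - 1e-4)
  # N = 4, balanced energies: exact enumeration gives 16/40
  expect_equal(monomer_fraction(4, 0, 0, method = "exact"), 0.4)
  expect_equal(monomer_fraction(4, 0, 0), 0.4, tolerance = 0.05)
  for (eD in c(0, 1.6, 3)) # moderate energies at N = 20
    expect_equal(monomer_fraction(20, 0, eD),
                 monomer_fraction(20, 0, eD, method = "exact"), tolerance = 0.05)
  expect_error(monomer_fraction(5, method = "exact"), "even")
})

test_that("physical unit mapping round-trips the diffusion coefficient", {
  u <- physical_units(40, 8, 20)
  expect_equal(u$spacing_nm, 2)
  expect_equal(u$timestep_s, 1.25e-7)
  # D recovered from (a, dt): a^2/(4 dt) in um^2/s
  expect_equal((u$spacing_nm * 1e-3)^2 / (4 * u$timestep_s) * 1e-0, 8,
               tolerance = 1e-12)
})
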
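hand_log <- function(r, d) {
  ev <- tibble::tibble(step = as.numeric(c(rbind(r, d))),
                       event_type = rep(c("reaction", "dissociation"), length(r)),
                       partner_id = 1L, x = 0L, y = 0L, comp_x = 0L, comp_y = 0L)
  ev[order(ev$step), ]
}

test_that("inter-reaction times follow the chosen convention", {
  ev <- hand_log(c(100, 400), c(150, 450))
  d2r <- inter_reaction_times(ev, "dissociation_to_reaction")
  expect_equal(d2r$wait, 250)
  r2r <- inter_reaction_times(ev, "reaction_to_reaction")
  expect_equal(r2r$wait, 300)
  expect_equal(nrow(inter_reaction_times(ev[0, ], "reaction_to_reaction")), 0)
  expect_equal(nrow(inter_reaction_times(ev[1:2, ], "reaction_to_reaction")), 0)
})

test_that("burst segmentation reproduces the hand example and its edge cases", {
  log <- make_fixture("hand_bursts")
  part <- segment_bursts(log, tau_crit = 500)
  expect_equal(part$bursts$amplitude, c(2L, 3L, 1L))
  expect_equal(part$gaps$duration, c(1850, 6910))
  expect_equal(part$bursts$censored, c(TRUE, FALSE, TRUE))
  # same partition under either waiting convention (dwells are short here)
  part2 <- segment_bursts(log, tau_crit = 500, convention = "reaction_to_reaction")
  expect_equal(part2$bursts$amplitude, part$bursts$amplitude)
  # tau_crit below every waiting time: all isolated
  expect_equal(segment_bursts(log, tau_crit = 5)$bursts$amplitude, rep(1L, 6))
  # tau_crit above every waiting time: one burst, no gaps
  one <- segment_bursts(log, tau_crit = 1e5)
  expect_equal(one$bursts$amplitude, 6L)
  expect_equal(nrow(one$gaps), 0)
})

test_that("segmentation is idempotent under a global time shift", {
  log <- make_fixture("hand_bursts")
  shifted <- log
  shifted$events$step <- shifted$events$step + 7777
  a <- segment_bursts(log, tau_crit = 500)
  b <- segment_bursts(shifted, tau_crit = 500)
  expect_equal(b$bursts$amplitude, a$bursts$amplitude)
  expect_equal(b$gaps$duration, a$gaps$duration)
  expect_equal(b$bursts$first_step, a$bursts$first_step + 7777)
})

test_that("waits, dwells and gaps partition the observed span exactly", {
  log <- make_fixture("tiny_sim")
  for (tc in c(50, 500, 5000)) {
    part <- segment_bursts(log, tau_crit = tc)
    ev <- log$events
    r <- ev$step[ev$event_type == "reaction"]
    d <- ev$step[ev$event_type == "dissociation"]
    m <- length(r)
    # consecutive reaction pairs either lie within a burst (dwell + wait)
    # or span a gap
    within <- inter_reaction_times(log)$wait <= tc
    dwell <- (d[seq_len(m - 1)] - r[seq_len(m - 1)])[within]
    waits <- inter_reaction_times(log)$wait[within]
    expect_equal(sum(waits) + sum(dwell) + sum(part$gaps$duration),
                 r[m] - r[1])
  }
})

test_that("burst summaries report means with bootstrap intervals", {
  part <- segment_bursts(make_fixture("hand_bursts"), tau_crit = 500)
  s <- summarize_bursts(part, n_boot = 500)
  expect_equal(s$mean_amplitude, 2)
  expect_equal(s$mean_gap, 4380)
  expect_true(s$amplitude_lo <= 2 && s$amplitude_hi >= 2)
  expect_true(s$gap_defined)
  lone <- segment_bursts(make_fixture("hand_bursts"), tau_crit = 1e5)
  expect_false(summarize_bursts(lone)$gap_defined)
})

test_that("ratio statistics scale as ratios should", {
  w <- c(10, 30, 50, 90, 120, 200, 40, 70)
  same <- ratio_stats(w, w, n_boot = 200)
  expect_equal(same$r_mean, 1)
  expect_equal(same$r_std, 1)
  twice <- ratio_stats(2 * w, w, n_boot = 200)
  expect_equal(twice$r_mean, 2)
  expect_equal(twice$r_std, 2)
  expect_error(ratio_stats(w, rep(5, 8)), "zero variance")
  expect_error(ratio_stats(w, numeric(0)), "two waiting")
})

test_that("percentile bootstrap behaves: degenerate series, containment, coverage", {
  const <- bootstrap_ci(rep(4, 10), mean, 200)
  expect_equal(as.numeric(const), c(4, 4))
  expect_true(attr(const, "degenerate"))
  x <- rexp(50, 1 / 20)
  ci <- bootstrap_ci(x, mean, 1000, seed = 2)
  expect_true(ci[1] <= mean(x) && ci[2] >= mean(x))
  expect_identical(bootstrap_ci(x, mean, 200, seed = 3),
                   bootstrap_ci(x, mean, 200, seed = 3))
  # coverage for the mean of exponential samples
  set.seed(10)
  hits <- vapply(1:300, function(i) {
    y <- rexp(40, 1 / 7)
    ci <- bootstrap_ci(y, mean, 400)
    ci[1] <= 7 && ci[2] >= 7
  }, logical(1))
  expect_gt(mean(hits), 0.87)
  expect_lt(mean(hits), 0.99)
})

test_that("local rate series scales trailing-window counts per compartment", {
  log <- make_fixture("tiny_sim")
  # synthesize an all-events table: three reactions in compartment (0,0)
  # inside the window, one outside, one in another compartment
  log$all_events <- tibble::tibble(step = c(920, 950, 1000, 600, 990),
                                   id = 0L, partner_id = 1L, x = 0L, y = 0L,
                                   comp_x = c(0L, 0L, 0L, 0L, 2L),
                                   comp_y = c(0L, 0L, 0L, 0L, 2L))
  lr <- local_rate_series(log, window = 100, scale = 10, at_steps = 1000)
  expect_equal(nrow(lr), 9)   # 3 x 3 compartments
  expect_equal(lr$rate[lr$comp_x == 0 & lr$comp_y == 0], 30)
  expect_equal(lr$rate[lr$comp_x == 2 & lr$comp_y == 2], 10)
  expect_equal(sum(lr$rate), 40)
  expect_error(local_rate_series(log, window = 0), "positive")
  # no events in the window: all-zero series
  lr0 <- local_rate_series(log, window = 100, at_steps = 300)
  expect_true(all(lr0$rate == 0))
})

test_that("ensemble-averaged counts reduce to the raw curve and to the mean rate", {
  log <- make_fixture("tiny_sim")
  raw <- ensemble_reaction_count(log, n_segments = 1)
  r <- log$events$step[log$events$event_type == "reaction"]
  expect_equal(max(raw$mean_count), length(r))
  expect_equal(raw$mean_count[floor(r[1])], 1)
  # homogeneous stream: straight line with slope = events/steps
  set.seed(8)
  steps <- sort(sample.int(1e5, 400))
  ev <- tibble::tibble(step = as.numeric(steps), event_type = "reaction",
                       partner_id = 1L, x = 0L, y = 0L, comp_x = 0L, comp_y = 0L)
  curve <- ensemble_reaction_count(ev, n_segments = 100, n_steps = 1e5)
  slope <- curve$mean_count[nrow(curve)] / curve$offset[nrow(curve)]
  expect_equal(slope, 400 / 1e5, tolerance = 0.05)
})

test_that("waiting-time histograms normalize to one", {
  h <- waiting_time_histogram(c(50, 120, 180), bin_width = 100)
  expect_equal(h$prob, c(1 / 3, 2 / 3))
  expect_equal(h$bin_left, c(0, 100))
  expect_equal(sum(h$prob), 1)
  expect_error(waiting_time_histogram(c(1, 2), bin_width = 0), "positive")
})

test_that("segment monomer fractions average to the whole-run fraction", {
  log <- make_fixture("tiny_sim")
  fr <- monomer_fraction_series(log, n_segments = 10)
  expect_equal(nrow(fr), 10)
  expect_true(all(fr$fraction >= 0 & fr$fraction <= 1))
  expect_equal(mean(fr$fraction), log$tracer_monomer_fraction, tolerance = 1e-3)
})
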
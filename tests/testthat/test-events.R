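test_that("zero-variability walks yield one peak per stride at the stride interval", {
  leg <- clean_leg_sim(n_strides = 70)
  res <- analyze_clean_leg(leg)
  expect_length(res$cycles$peak_times, 70L)
  gaps <- diff(res$cycles$peak_times)
  expect_lt(max(abs(gaps - 0.98)), 0.02 + 1e-9)
})

test_that("detected event times match the generator ground truth within one sample", {
  leg <- clean_leg_sim(n_strides = 30)
  res <- analyze_clean_leg(leg)
  truth <- attr(leg, "truth")
  cyc <- res$cycles$cycles
  # match each detected cycle to the nearest true cycle via mid-swing times
  match_idx <- vapply(cyc$t_midswing,
                      function(t) which.min(abs(truth$t_midswing - t)), 0L)
  expect_lt(max(abs(cyc$t_midswing - truth$t_midswing[match_idx])), 0.02 + 1e-9)
  expect_lt(max(abs(cyc$t_toeoff - truth$t_toeoff[match_idx])), 0.02 + 1e-9)
  expect_lt(max(abs(cyc$t_heelstrike - truth$t_heelstrike[match_idx])),
            0.02 + 1e-9)
})

test_that("noise does not change the detected peak count at fixed seed", {
  p <- default_params("control")
  counts <- vapply(c(0, 15), function(ns) {
    cfg <- sim_config(noise_sd = ns, stride_time_cv = 0, amplitude_cv = 0,
                      seed = 17)
    leg <- simulate_leg(p, 40, cfg, leg = "left", seed = 17)
    res <- analyze_clean_leg(leg, max_sd = 20)
    length(res$cycles$peak_times)
  }, 0L)
  expect_equal(counts[1], counts[2])
})

test_that("a flat signal has too few strides", {
  flat <- signal_nav(rep(0, 500))
  expect_error(detect_midswing_peaks(flat), "too few strides")
})

test_that("full-pipeline recovery matches the realized template for every preset", {
  for (col in list(c("control", "normal"), c("vn", "lvn"), c("vn", "rvn"))) {
    p <- default_params(col[1], col[2])
    tpl <- make_cycle_template(p)
    r <- tpl$realized
    lesion <- switch(col[2], normal = "none", lvn = "left", rvn = "right")
    cfg <- sim_config(group = col[1], lesion_side = lesion,
                      left_params = p, right_params = p,
                      noise_sd = 0, stride_time_cv = 0, amplitude_cv = 0,
                      seed = 19)
    leg <- simulate_leg(p, 25, cfg, leg = "left", seed = 19)
    res <- analyze_clean_leg(leg)
    cyc <- res$cycles$cycles
    rel <- function(a, b) abs(a - b) / abs(b)
    expect_lt(rel(mean(cyc$max_nav), r$a_midswing), 0.01)
    expect_lt(rel(mean(cyc$min_nav), r$a_toeoff), 0.01)
    expect_lt(rel(mean(cyc$up_slope), r$up_slope), 0.01)
    expect_lt(rel(mean(cyc$down_slope), r$down_slope), 0.01)
    expect_lt(rel(mean(cyc$stride_time), r$stride_time), 0.01)
    expect_lt(rel(mean(cyc$swing_time), r$swing_time), 0.01)
    expect_lt(rel(mean(cyc$stance_time), r$stance_time), 0.01)
    # against the published preset means: amplitudes exact, timing within 2%
    expect_lt(rel(mean(cyc$max_nav), p$a_midswing), 1e-9)
    expect_lt(rel(mean(cyc$min_nav), p$a_toeoff), 1e-9)
    expect_lt(rel(mean(cyc$stride_time), p$stride_time), 0.02)
    expect_lt(rel(mean(cyc$stance_time), p$stance_time), 0.02)
    expect_lt(rel(mean(cyc$stance_ratio),
                  100 * p$stance_time / p$stride_time), 0.02)
  }
})

test_that("recovery degrades gracefully under noise and jitter", {
  for (col in list(c("control", "normal"), c("vn", "lvn"), c("vn", "rvn"))) {
    p <- default_params(col[1], col[2])
    r <- make_cycle_template(p)$realized
    cfg <- sim_config(left_params = p, right_params = p, noise_sd = 10,
                      stride_time_cv = 0.03, amplitude_cv = 0.03, seed = 23)
    leg <- simulate_leg(p, 40, cfg, leg = "left", seed = 23)
    res <- analyze_clean_leg(leg, max_sd = 15)
    cyc <- res$cycles$cycles
    rel <- function(a, b) abs(a - b) / abs(b)
    expect_lt(rel(mean(cyc$max_nav), r$a_midswing), 0.05)
    expect_lt(rel(mean(cyc$min_nav), r$a_toeoff), 0.05)
    expect_lt(rel(mean(cyc$up_slope), r$up_slope), 0.05)
    expect_lt(rel(mean(cyc$stride_time), r$stride_time), 0.05)
    expect_lt(rel(mean(cyc$stance_time), r$stance_time), 0.05)
  }
})

test_that("definitional identities hold for every emitted cycle", {
  cfg <- sim_config(noise_sd = 8, stride_time_cv = 0.05, amplitude_cv = 0.05,
                    seed = 29)
  leg <- simulate_leg(default_params("control"), 40, cfg, leg = "left",
                      seed = 29)
  res <- analyze_clean_leg(leg)
  cyc <- res$cycles$cycles
  expect_equal(cyc$swing_time + cyc$stance_time, cyc$stride_time)
  expect_equal(cyc$stance_ratio, 100 * cyc$stance_time / cyc$stride_time)
  expect_true(all(cyc$up_slope > 0))
  expect_true(all(cyc$down_slope < 0))
  expect_true(all(cyc$min_nav < cyc$max_nav))
})

test_that("a heel-strike trough deeper than toe-off is flagged, not returned", {
  # adversarial waveform: second trough deeper than the first
  one <- c(rep(0, 20), seq(0, -100, length.out = 5),
           seq(-100, 300, length.out = 8), seq(300, -150, length.out = 8),
           seq(-150, 0, length.out = 5), rep(0, 4))
  nav <- signal_nav(rep(one, 6))
  peaks <- detect_midswing_peaks(nav)
  i <- 3L
  ev <- detect_cycle_events(nav, peaks[i], peaks[i - 1], peaks[i + 1])
  expect_false(ev$valid)
  expect_match(ev$reason, "not the cycle minimum")
})

test_that("the cycle ensemble reproduces the template shape", {
  leg <- clean_leg_sim(n_strides = 30)
  res <- analyze_clean_leg(leg)
  cyc <- res$cycles$cycles
  starts <- c(cyc$t_toeoff, cyc$t_toeoff[nrow(cyc)] + cyc$stride_time[nrow(cyc)])
  ens <- cycle_ensemble(res$nav, starts)
  expect_lt(max(ens$sd), 1e-6)
  # phase-grid interpolation can clip the sharp mid-swing peak by at most
  # (max slope) * (half a phase step); assert the derivable bound
  phase_step <- 0.98 / 100
  bound <- 3005 * phase_step / 2 / 368.6
  expect_lt(abs(max(ens$mean) - 368.6) / 368.6, bound)
  ens2 <- cycle_ensemble(res$nav, starts, n_points = 202L)
  expect_lt(abs(max(ens2$mean) - max(ens$mean)) / max(ens$mean), bound)
  expect_error(cycle_ensemble(res$nav, starts[1:3]), "at least 3 cycles")
})

test_that("walk summaries aggregate velocity and timing variances correctly", {
  cfg <- sim_config(noise_sd = 0, stride_time_cv = 0, amplitude_cv = 0,
                    seed = 31)
  rec <- simulate_walk(cfg)
  aligned <- align_pair(rec$left, rec$right,
                        corridor_length = rec$corridor_length)
  an <- suppressMessages(analyze_recording(aligned))
  s <- an$summary$left
  expect_equal(s$gait_velocity, 1.11, tolerance = 0.02)
  expect_equal(s$var_toeoff_time, 0)
  expect_equal(s$var_heelstrike_time, 0)
  expect_gte(s$n_strides, 79L)

  # event-timing variance grows with stride-time variability at fixed seed
  vs <- vapply(c(0.02, 0.1), function(cv) {
    cfg <- sim_config(noise_sd = 0, stride_time_cv = cv, amplitude_cv = 0,
                      seed = 37, corridor_length = 40)
    rec <- simulate_walk(cfg)
    an <- suppressMessages(analyze_recording(
      align_pair(rec$left, rec$right, corridor_length = 40)))
    an$summary$left$var_toeoff_time
  }, 0)
  expect_gt(vs[2], vs[1])
})
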
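test_that("the shake spike is found at the end of the stationary lead-in", {
  leg <- clean_leg_sim(n_strides = 5)
  expect_equal(detect_sync_start(leg), 5.0, tolerance = 0.02)

  cfg <- sim_config(noise_sd = 0.5, stride_time_cv = 0, amplitude_cv = 0,
                    stationary_lead = 3, seed = 8)
  leg2 <- simulate_leg(default_params("control"), 5, cfg, leg = "left",
                       seed = 8)
  expect_lt(abs(detect_sync_start(leg2) - 3.0), 0.02 + 1e-9)
})

test_that("a recording without a spike raises sync-not-found", {
  flat <- angvel_series(seq(0, 1, by = 0.02), rep(0, 51), rep(0, 51),
                        rep(0, 51), leg = "left")
  expect_error(detect_sync_start(flat), "sync not found")
})

test_that("legs shaken together synchronize to within one sample", {
  cfg <- sim_config(noise_sd = 2, seed = 4, corridor_length = 15)
  rec <- simulate_walk(cfg)
  t0l <- detect_sync_start(rec$left)
  t0r <- detect_sync_start(rec$right)
  expect_lt(abs(t0l - t0r), 0.02 + 1e-9)
})

test_that("stationary offsets are recovered and walking windows rejected", {
  cfg <- sim_config(noise_sd = 0.1, stride_time_cv = 0, amplitude_cv = 0,
                    seed = 10)
  leg <- simulate_leg(default_params("control"), 10, cfg, leg = "left",
                      seed = 10)
  off <- estimate_offsets(leg, c(0.5, 4.5))
  expect_lt(abs(off[["ox"]] - 2), 0.1)
  expect_lt(abs(off[["oy"]] - -3), 0.1)
  expect_lt(abs(off[["oz"]] - 1.5), 0.1)

  truth <- attr(leg, "truth")
  expect_error(
    estimate_offsets(leg, truth$walk_start + c(0.5, 3.5)),
    "not stationary")

  flat <- angvel_series(seq(0, 2, by = 0.02), rep(0, 101), rep(0, 101),
                        rep(0, 101), leg = "left")
  expect_equal(unname(estimate_offsets(flat, c(0, 2))), c(0, 0, 0))

  expect_error(estimate_offsets(leg, c(0.5, 1.2)), "at least 1 s")
  expect_error(estimate_offsets(leg, c(-5, 3)), "outside the recording")
})

test_that("alignment maps both spikes to t = 0 and is idempotent", {
  cfg <- sim_config(noise_sd = 0, stride_time_cv = 0, amplitude_cv = 0,
                    seed = 12, corridor_length = 10)
  rec <- simulate_walk(cfg)
  aligned <- align_pair(rec$left, rec$right,
                        corridor_length = rec$corridor_length)
  expect_equal(detect_sync_start(aligned$left), 0, tolerance = 1e-9)
  expect_equal(detect_sync_start(aligned$right), 0, tolerance = 1e-9)

  twice <- align_pair(aligned$left, aligned$right,
                      corridor_length = rec$corridor_length)
  expect_equal(twice$left$time, aligned$left$time)
  expect_identical(twice$left$gz, aligned$left$gz)
  expect_identical(twice$right$gz, aligned$right$gz)
})

test_that("a file-level delay on one sensor is removed by alignment", {
  cfg <- sim_config(noise_sd = 0, stride_time_cv = 0, amplitude_cv = 0,
                    seed = 13, corridor_length = 10)
  rec <- simulate_walk(cfg)
  delayed <- angvel_series(rec$right$time + 0.4, rec$right$gx, rec$right$gy,
                           rec$right$gz, leg = "right")
  aligned <- align_pair(rec$left, delayed,
                        corridor_length = rec$corridor_length)
  ref <- align_pair(rec$left, rec$right,
                    corridor_length = rec$corridor_length)
  expect_equal(detect_sync_start(aligned$right), 0, tolerance = 1e-9)
  n <- min(length(aligned$right$gz), length(ref$right$gz))
  expect_identical(aligned$right$gz[1:n], ref$right$gz[1:n])
})

test_that("alignment propagates a missing spike as an error", {
  cfg <- sim_config(noise_sd = 0, sync_spike_amplitude = 0, seed = 14,
                    corridor_length = 10)
  rec <- simulate_walk(cfg)
  rec_ok <- simulate_walk(sim_config(noise_sd = 0, seed = 14,
                                     corridor_length = 10))
  expect_error(align_pair(rec_ok$left, rec$right), "sync not found")
})
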
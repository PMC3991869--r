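test_that("zero-variability strides are sample-identical and seeded runs reproduce", {
  cfg <- sim_config(noise_sd = 0, stride_time_cv = 0, amplitude_cv = 0,
                    seed = 3)
  p <- default_params("control")
  leg <- simulate_leg(p, 3, cfg, leg = "left", seed = 3)
  truth <- attr(leg, "truth")
  n <- round(p$stride_time / cfg$sample_interval)
  i0 <- which.min(abs(leg$time - truth$walk_start))
  strides <- matrix(leg$gz[i0:(i0 + 3 * n - 1)], ncol = 3)
  expect_equal(strides[, 1], strides[, 2])
  expect_equal(strides[, 2], strides[, 3])

  leg2 <- simulate_leg(p, 3, cfg, leg = "left", seed = 3)
  expect_identical(leg$gz, leg2$gz)
  expect_identical(leg$gx, leg2$gx)
  # with stochastic components active, the seed drives the realization
  cfgn <- sim_config(noise_sd = 4, stride_time_cv = 0.02, seed = 3)
  na <- simulate_leg(p, 3, cfgn, leg = "left", seed = 3)
  nb <- simulate_leg(p, 3, cfgn, leg = "left", seed = 3)
  nc <- simulate_leg(p, 3, cfgn, leg = "left", seed = 4)
  expect_identical(na$gz, nb$gz)
  expect_false(identical(na$gz, nc$gz))
})

test_that("the walking segment lasts the sum of the jittered stride times", {
  cfg <- sim_config(noise_sd = 0, stride_time_cv = 0.02, amplitude_cv = 0,
                    seed = 5)
  leg <- simulate_leg(default_params("control"), 70, cfg, leg = "left",
                      seed = 5)
  truth <- attr(leg, "truth")
  dur <- sum(vapply(truth$realized, `[[`, 0, "stride_time"))
  expect_lt(abs(dur - 70 * 0.98), 0.98)  # within one stride of the mean total
  # truth bookkeeping is self-consistent
  expect_equal(truth$cycle_starts[70] + truth$realized[[70]]$stride_time -
                 truth$cycle_starts[1], dur)
})

test_that("stride-time variability degrades the stride-time estimate monotonically", {
  sds <- vapply(c(0, 0.02, 0.05, 0.10), function(cv) {
    cfg <- sim_config(noise_sd = 0, stride_time_cv = cv, amplitude_cv = 0,
                      seed = 9)
    leg <- simulate_leg(default_params("control"), 40, cfg, leg = "left",
                        seed = 9)
    res <- analyze_clean_leg(leg)
    sd(res$cycles$cycles$stride_time)
  }, 0)
  expect_true(all(diff(sds) > 0))
})

test_that("simulated walks have reciprocally phased legs and the expected stride count", {
  cfg <- sim_config(noise_sd = 0, stride_time_cv = 0, amplitude_cv = 0,
                    seed = 2)
  rec <- simulate_walk(cfg)
  tl <- attr(rec$left, "truth"); tr <- attr(rec$right, "truth")
  # ceil(88.8 / (1.11 * 0.98)) strides per leg
  expect_length(tl$cycle_starts, 82L)
  expect_length(tr$cycle_starts, 82L)
  # right-leg mid-swing peaks offset by half a stride (grid-quantized)
  offs <- tr$t_midswing[1:40] - tl$t_midswing[1:40]
  expect_lt(max(abs(offs - 0.98 / 2)), 0.02 + 1e-9)
})

test_that("vestibular-neuritis walks use the lesion-side preset", {
  cfg <- sim_config(group = "vn", lesion_side = "left", noise_sd = 0,
                    stride_time_cv = 0, amplitude_cv = 0, seed = 2)
  rec <- simulate_walk(cfg)
  tl <- attr(rec$left, "truth")
  expect_equal(tl$realized[[1]]$a_midswing, 258.6)
  expect_equal(tl$realized[[1]]$a_toeoff, -125.8)
  # contralateral leg is interpolated halfway toward the control template
  tr <- attr(rec$right, "truth")
  expect_equal(tr$realized[[1]]$a_midswing, (258.6 + 368.6) / 2)
  expect_error(sim_config(group = "vn", lesion_side = "none"),
               "lesion_side")
})

test_that("subject-level draws stay near the preset and respect invariants", {
  draws <- lapply(1:20, function(i) draw_subject_params("normal", seed = i))
  for (d in draws) expect_silent(validate_cycle_params(d))
  ms <- vapply(draws, `[[`, 0, "a_midswing")
  expect_lt(abs(mean(ms) - 368.6), 3 * 42.5 / sqrt(20))
})
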
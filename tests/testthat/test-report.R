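test_that("a simulated cohort reproduces its preset group means", {
  coh <- simulate_cohort(n_control = 6, n_lvn = 4, n_rvn = 4, seed = 42,
                         corridor_length = 30)
  expect_equal(nrow(coh), 14L)
  report <- build_report(coh)
  tab <- report$table
  ref <- gait_reference_values()
  for (param in c("max_nav", "min_nav", "stride_time", "stance_time")) {
    for (grp in c("normal", "lvn", "rvn")) {
      n <- tab[[paste0(grp, "_n")]][tab$parameter == param]
      sem <- ref[[paste0(grp, "_sd")]][ref$parameter == param] / sqrt(n)
      got <- tab[[paste0(grp, "_mean")]][tab$parameter == param]
      want <- ref[[paste0(grp, "_mean")]][ref$parameter == param]
      # 2-SEM band: subject draws use the published between-subject SDs
      expect_lt(abs(got - want), 2 * sem + 1e-9)
    }
  }
  # group-level velocity contrast survives the round trip
  v <- tapply(coh$gait_velocity, coh$group, mean)
  expect_gt(v[["normal"]], v[["lvn"]])
  expect_gt(v[["normal"]], v[["rvn"]])
})

test_that("parameters are routed to the prescribed statistical procedures", {
  set.seed(31)
  fake <- do.call(rbind, lapply(c("a", "b", "c"), function(g) {
    n <- 8
    data.frame(group = g, max_nav = rnorm(n, 350, 40),
               min_nav = rnorm(n, -170, 30), down_slope = rnorm(n, -3000, 300),
               up_slope = rnorm(n, 2900, 500), stride_time = rnorm(n, 1, 0.06),
               swing_time = rnorm(n, 0.4, 0.05),
               stance_time = rnorm(n, 0.6, 0.05),
               stance_ratio = rnorm(n, 60, 2))
  }))
  report <- build_report(fake)
  tab <- report$table
  expect_setequal(tab$parameter, names(default_routing()))
  expect_true(all(tab$test[tab$parameter %in% c("stance_time", "stance_ratio")] ==
                    "mann-whitney"))
  expect_true(all(tab$posthoc[tab$parameter %in% c("stance_time", "stance_ratio")] ==
                    "MWU+Bonferroni"))
  expect_true(all(tab$test[tab$parameter == "max_nav"] %in%
                    c("anova", "kruskal")))
  mwu <- report$details$stance_time$pairwise
  expect_true(all(mwu$p_adjusted >= mwu$p))
  expect_true(all(tab$min_p >= 0 & tab$min_p <= 1))
})

test_that("null cohorts rarely produce significant comparisons", {
  set.seed(37)
  n_reject <- 0L
  for (rep in 1:20) {
    null_cohort <- do.call(rbind, lapply(list(c("normal", 10), c("lvn", 5),
                                              c("rvn", 5)), function(g) {
      n <- as.integer(g[2])
      data.frame(group = g[1], max_nav = rnorm(n, 368.6, 42.5),
                 min_nav = rnorm(n, -172.3, 34.5),
                 down_slope = rnorm(n, -3003, 341.7),
                 up_slope = rnorm(n, 2968.7, 973.9),
                 stride_time = rnorm(n, 0.98, 0.062),
                 swing_time = rnorm(n, 0.389, 0.06),
                 stance_time = rnorm(n, 0.591, 0.044),
                 stance_ratio = rnorm(n, 60.4, 2))
    }))
    report <- build_report(null_cohort)
    # multiplicity-adjusted comparisons only (the Bonferroni-corrected
    # rank tests); each parameter's family is controlled at 0.05, so a
    # cohort with any adjusted p < 0.05 occurs with probability ~0.10
    any_sig <- any(vapply(report$details, function(d) {
      if (d$route == "mwu") any(d$pairwise$p_adjusted < 0.05) else FALSE
    }, logical(1)))
    if (any_sig) n_reject <- n_reject + 1L
  }
  expect_lte(n_reject, 5L)  # 99th binomial percentile at rate 0.10, n = 20
})

test_that("degenerate report inputs are rejected", {
  one <- data.frame(group = "a", max_nav = rnorm(5), min_nav = rnorm(5),
                    down_slope = rnorm(5), up_slope = rnorm(5),
                    stride_time = rnorm(5), swing_time = rnorm(5),
                    stance_time = rnorm(5), stance_ratio = rnorm(5))
  expect_error(build_report(one), "at least 2 groups")
  expect_error(build_report(data.frame(group = c("a", "b"), x = 1:2)),
               "missing parameter column")
})

test_that("reports serialize to CSV and JSON", {
  set.seed(41)
  fake <- do.call(rbind, lapply(c("a", "b"), function(g) {
    data.frame(group = g, max_nav = rnorm(6, 350, 40),
               min_nav = rnorm(6, -170, 30), down_slope = rnorm(6, -3000, 300),
               up_slope = rnorm(6, 2900, 500), stride_time = rnorm(6, 1, 0.06),
               swing_time = rnorm(6, 0.4, 0.05),
               stance_time = rnorm(6, 0.6, 0.05),
               stance_ratio = rnorm(6, 60, 2))
  }))
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  run_compare(fake, out_csv = csv, out_json = json)
  expect_equal(nrow(utils::read.csv(csv)), 8L)
  parsed <- jsonlite::read_json(json)
  expect_named(parsed, c("table", "pairwise"))
  expect_length(parsed$pairwise, 8L)
})
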
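test_that("Mann-Whitney U matches hand-enumerated exact cases", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 20)  # C(6,3) = 20 arrangements, one as extreme
  expect_equal(res$method, "exact")

  tied <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tied$method, "normal-approx")
  expect_gte(tied$p, 0.99)

  set.seed(1)
  x <- rnorm(8); y <- rnorm(8)
  p_exact <- mann_whitney_u(x, y)$p
  p_approx <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  expect_lt(abs(p_exact - p_approx), 0.02)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney agrees with the brute-force permutation oracle", {
  set.seed(99)
  for (nx in 2:5) {
    for (ny in 2:5) {
      x <- round(rnorm(nx), 6); y <- round(rnorm(ny) + 0.5, 6)
      res <- mann_whitney_u(x, y)
      expect_equal(res$method, "exact")
      expect_equal(res$p, mwu_brute_force(x, y), tolerance = 1e-12,
                   info = sprintf("nx=%d ny=%d", nx, ny))
    }
  }
})

test_that("the normality check separates normal from exponential samples", {
  set.seed(7)
  expect_gt(ks_normality(rnorm(500)), 0.05)
  expect_lt(ks_normality(rexp(500)), 0.01)
  expect_error(ks_normality(rep(1, 10)), "degenerate")
  expect_error(ks_normality(c(1, 2, 3)), "at least 5")
})

test_that("the variance-equality routing reflects the group spreads", {
  set.seed(11)
  a <- rnorm(50, sd = 1); b <- rnorm(50, sd = 1)
  expect_true(variance_equal(list(a, b))$equal)
  c4 <- rnorm(50, sd = 4)
  res <- variance_equal(list(a, c4))
  expect_false(res$equal)
  expect_lt(res$p, 0.01)
  same <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(variance_equal(same)$p, 1)
  expect_error(variance_equal(list(a, 1)), "n >= 2")
})

test_that("the omnibus test routes by normality and handles identical groups", {
  res <- omnibus_compare(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res$test, "anova")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  set.seed(13)
  g <- list(rnorm(20), rnorm(20), rnorm(20, mean = 2))
  res <- omnibus_compare(g)
  expect_lt(res$p, 0.001)

  # strongly non-normal groups take the rank-based branch
  set.seed(17)
  gnn <- list(rexp(30)^2, rexp(30)^2, rexp(30)^2 + 2)
  expect_equal(omnibus_compare(gnn)$test, "kruskal")

  tied <- omnibus_compare(list(c(1, 1, 1), c(1, 1, 1)), method = "kruskal")
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p, 1)
})

test_that("ANOVA with two groups reproduces the squared pooled t statistic", {
  set.seed(19)
  x <- rnorm(15); y <- rnorm(12, mean = 0.8)
  f_stat <- omnibus_compare(list(x, y), method = "anova")$statistic
  t_stat <- stats::t.test(x, y, var.equal = TRUE)$statistic
  expect_lt(abs(f_stat - t_stat^2), 1e-9)
})

test_that("post-hoc procedures behave per their variance assumptions", {
  same <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(posthoc_compare(same, equal_variance = TRUE)$p, 1)

  set.seed(23)
  x <- rnorm(10); y <- rnorm(10, 0.5)
  lsd <- posthoc_compare(list(x, y), equal_variance = TRUE)
  expect_equal(lsd$p, stats::t.test(x, y, var.equal = TRUE)$p.value,
               tolerance = 1e-12)

  g3 <- list(rnorm(10), rnorm(8, 0.5, 2), rnorm(12, 1, 0.5))
  t3 <- posthoc_compare(g3, equal_variance = FALSE)
  welch <- utils::combn(3, 2)
  for (j in 1:3) {
    pw <- stats::t.test(g3[[welch[1, j]]], g3[[welch[2, j]]])$p.value
    expect_gte(t3$p[j] + 1e-12, pw)  # maximum-modulus reference is conservative
  }
  expect_error(posthoc_compare(list(1:3), TRUE), "at least 2 groups")
})

test_that("Bonferroni adjustment clips at one and never shrinks a p-value", {
  expect_equal(bonferroni_adjust(c(0.01, 0.04), 2), c(0.02, 0.08))
  expect_equal(bonferroni_adjust(0.9, 3), 1)
  set.seed(29)
  p <- runif(20)
  expect_true(all(bonferroni_adjust(p, 20) >= p))
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), "at least")
})
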
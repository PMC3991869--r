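#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples with mid-rank tie
#' handling. The p-value is exact (by enumeration of the U distribution)
#' when the combined sample size is at most 20 and there are no ties, and a
#' tie-corrected normal approximation with continuity correction otherwise.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A list with `U` (the Mann-Whitney U statistic for `x`), `p`,
#'   and `method` (`"exact"` or `"normal-approx"`).
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  .vg_check(length(x) >= 1L && length(y) >= 1L,
            "mann_whitney_u: both samples must be non-empty")
  .vg_check(all(is.finite(x)) && all(is.finite(y)),
            "mann_whitney_u: non-finite values")
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 20L) && !has_ties
  res <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = TRUE))
  list(U = unname(res$statistic), p = res$p.value,
       method = if (exact) "exact" else "normal-approx")
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' One-sample KS test against a normal distribution with mean and SD
#' estimated from the data (Lilliefors correction of the null distribution).
#'
#' @param x Numeric sample with at least 5 distinct-enough values.
#' @return The p-value.
#' @export
ks_normality <- function(x) {
  .vg_check(length(x) >= 5L, "ks_normality: need at least 5 observations")
  .vg_check(all(is.finite(x)), "ks_normality: non-finite values")
  .vg_check(stats::sd(x) > 0, "ks_normality: degenerate (constant) sample")
  nortest::lillie.test(x)$p.value
}

#' Variance-equality decision (Brown-Forsythe)
#'
#' Median-centred Levene test across groups at alpha = 0.05, used to route
#' post-hoc comparisons between the equal-variance (LSD) and
#' unequal-variance (Dunnett T3) procedures.
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @param alpha Decision level (default 0.05).
#' @return A list with `equal` (logical), `p` and `statistic`.
#' @export
variance_equal <- function(groups, alpha = 0.05) {
  .vg_check(is.list(groups) && length(groups) >= 2L,
            "variance_equal: need at least 2 groups")
  .vg_check(all(vapply(groups, length, 0L) >= 2L),
            "variance_equal: every group needs n >= 2")
  values <- unlist(groups)
  labels <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  lt <- car::leveneTest(values, labels, center = stats::median)
  p <- lt[["Pr(>F)"]][1]
  list(equal = p >= alpha, p = p, statistic = lt[["F value"]][1])
}

#' Omnibus group comparison with normality routing
#'
#' One-way comparison of two or more groups. With `method = "auto"`, each
#' group is checked with [ks_normality()]; if all pass at alpha = 0.05 a
#' one-way ANOVA is used, otherwise Kruskal-Wallis. Groups too small for the
#' normality check (n < 5) default to the parametric branch. The branch
#' taken is recorded in the result.
#'
#' @param groups List of numeric vectors, each of length >= 3.
#' @param method `"auto"` (default), `"anova"` or `"kruskal"` to force a
#'   branch.
#' @param alpha Normality-decision level (default 0.05).
#' @return A list with `test` (`"anova"` or `"kruskal"`), `statistic`
#'   (F or H), `p`, and `normality_p` (per-group, `NA` where not assessable).
#' @export
omnibus_compare <- function(groups, method = c("auto", "anova", "kruskal"),
                            alpha = 0.05) {
  method <- match.arg(method)
  .vg_check(is.list(groups) && length(groups) >= 2L,
            "omnibus_compare: need at least 2 groups")
  .vg_check(all(vapply(groups, length, 0L) >= 3L),
            "omnibus_compare: every group needs n >= 3")
  norm_p <- vapply(groups, function(g) {
    if (length(g) < 5L || stats::sd(g) == 0) NA_real_ else ks_normality(g)
  }, 0)
  if (method == "auto") {
    all_normal <- all(is.na(norm_p) | norm_p >= alpha)
    method <- if (all_normal) "anova" else "kruskal"
  }
  values <- unlist(groups)
  labels <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (method == "anova") {
    fit <- stats::aov(values ~ labels)
    s <- summary(fit)[[1]]
    stat <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
    if (stats::var(values) == 0) { stat <- 0; p <- 1 }  # all-identical guard
  } else {
    kt <- stats::kruskal.test(values, labels)
    stat <- unname(kt$statistic); p <- kt$p.value
    if (is.nan(p)) { stat <- 0; p <- 1 }  # fully tied samples
  }
  list(test = method, statistic = stat, p = p, normality_p = norm_p)
}

# studentized maximum modulus CDF: P(max_{j<=k} |Z_j| / (chi_nu/sqrt(nu)) <= q)
# with independent standard normals Z_j sharing one chi denominator
.psmm <- function(q, k, df) {
  if (!is.finite(q) || q <= 0) return(0)
  dens <- function(s) {
    exp((1 - df / 2) * log(2) - lgamma(df / 2) + df / 2 * log(df) +
          (df - 1) * log(s) - df * s^2 / 2)
  }
  f <- function(s) (2 * stats::pnorm(q * s) - 1)^k * dens(s)
  stats::integrate(f, 0, Inf, rel.tol = 1e-8)$value
}

#' Pairwise post-hoc comparisons (Fisher LSD or Dunnett T3)
#'
#' With `equal_variance = TRUE`, Fisher's least-significant-difference
#' procedure: pairwise t statistics with the pooled within-group variance
#' (the ANOVA mean-square error) and no multiplicity adjustment. Otherwise
#' Dunnett's T3: Welch-type pairwise t statistics with Welch degrees of
#' freedom, referred to the studentized-maximum-modulus distribution over
#' the number of comparisons.
#'
#' @param groups List of >= 2 numeric vectors (each n >= 2).
#' @param equal_variance Logical routing decision (see [variance_equal()]).
#' @param labels Optional group names.
#' @return A data frame with one row per pair: `group1`, `group2`,
#'   `mean_diff`, `t`, `df`, `p`, `method`.
#' @export
posthoc_compare <- function(groups, equal_variance, labels = NULL) {
  .vg_check(is.list(groups) && length(groups) >= 2L,
            "posthoc_compare: need at least 2 groups")
  .vg_check(all(vapply(groups, length, 0L) >= 2L),
            "posthoc_compare: every group needs n >= 2")
  k <- length(groups)
  if (is.null(labels)) labels <- names(groups) %||% paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  ns <- vapply(groups, length, 0L)
  means <- vapply(groups, mean, 0)
  vars <- vapply(groups, stats::var, 0)
  rows <- vector("list", m)
  if (equal_variance) {
    df_err <- sum(ns) - k
    mse <- sum((ns - 1) * vars) / df_err
    for (j in seq_len(m)) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      se <- sqrt(mse * (1 / ns[i1] + 1 / ns[i2]))
      tval <- (means[i1] - means[i2]) / se
      p <- if (se == 0) 1 else 2 * stats::pt(-abs(tval), df_err)
      rows[[j]] <- data.frame(
        group1 = labels[i1], group2 = labels[i2],
        mean_diff = means[i1] - means[i2],
        t = if (se == 0) 0 else tval, df = df_err, p = p, method = "LSD")
    }
  } else {
    for (j in seq_len(m)) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      v1 <- vars[i1] / ns[i1]; v2 <- vars[i2] / ns[i2]
      se <- sqrt(v1 + v2)
      df_w <- (v1 + v2)^2 / (v1^2 / (ns[i1] - 1) + v2^2 / (ns[i2] - 1))
      tval <- if (se == 0) 0 else (means[i1] - means[i2]) / se
      p <- if (se == 0) 1 else 1 - .psmm(abs(tval), m, df_w)
      rows[[j]] <- data.frame(
        group1 = labels[i1], group2 = labels[i2],
        mean_diff = means[i1] - means[i2],
        t = tval, df = if (se == 0) NA_real_ else df_w,
        p = min(max(p, 0), 1), method = "DunnettT3")
    }
  }
  do.call(rbind, rows)
}

#' Bonferroni adjustment
#'
#' `adjusted = min(1, p * m)` for a family of `m` comparisons.
#'
#' @param pvals Numeric vector of raw p-values.
#' @param m Family size; must be at least `length(pvals)` (default).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  .vg_check(m >= length(pvals),
            "bonferroni_adjust: m must be at least length(pvals)")
  pmin(1, pvals * m)
}
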
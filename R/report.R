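#' Default parameter-to-test routing for the group report
#'
#' The amplitude, slope, stride and swing parameters go through the
#' normality-routed omnibus test (ANOVA or Kruskal-Wallis) with a
#' variance-dependent post-hoc (LSD or Dunnett T3); stance time and stance
#' ratio go through pairwise Mann-Whitney U tests with Bonferroni
#' correction. The routing is frozen per parameter rather than re-decided
#' per dataset, matching common clinical-gait reporting practice; pass a
#' modified copy to [build_report()] to override.
#'
#' @return Named character vector mapping parameter name to `"omnibus"` or
#'   `"mwu"`.
#' @export
default_routing <- function() {
  c(max_nav = "omnibus", min_nav = "omnibus", down_slope = "omnibus",
    up_slope = "omnibus", stride_time = "omnibus", swing_time = "omnibus",
    stance_time = "mwu", stance_ratio = "mwu")
}

#' Group-comparison report over per-subject gait summaries
#'
#' Builds the standard gait-parameter comparison table: per-group mean, SD
#' and n for each parameter, plus the routed statistics — omnibus test
#' (ANOVA or Kruskal-Wallis by per-group normality), variance-equality
#' decision (Brown-Forsythe), post-hoc pairwise comparisons (LSD when
#' variances are equal, Dunnett T3 otherwise) for the amplitude/slope/timing
#' parameters, and pairwise Mann-Whitney U with Bonferroni correction
#' (family size = number of pairs) for stance time and stance ratio.
#'
#' @param data Data frame with one row per subject: the parameter columns
#'   named in `routing` plus a group column.
#' @param group_col Name of the group column (default `"group"`).
#' @param routing Named vector as returned by [default_routing()].
#' @return A list of class `gait_report`: `table` (per-parameter data frame
#'   with group means/SDs, test names and p-values) and `details` (per
#'   parameter: the omnibus/variance results and pairwise data frame).
#' @export
build_report <- function(data, group_col = "group", routing = default_routing()) {
  .vg_check(is.data.frame(data) && group_col %in% names(data),
            sprintf("build_report: data must contain a '%s' column", group_col))
  grp <- factor(data[[group_col]])
  .vg_check(nlevels(grp) >= 2L,
            "build_report: need at least 2 groups represented")
  params <- names(routing)
  missing_cols <- setdiff(params, names(data))
  .vg_check(length(missing_cols) == 0L,
            sprintf("build_report: missing parameter column(s): %s",
                    paste(missing_cols, collapse = ", ")))
  lv <- levels(grp)
  rows <- list(); details <- list()
  for (param in params) {
    groups <- split(data[[param]], grp)
    means <- vapply(groups, mean, 0)
    sds <- vapply(groups, stats::sd, 0)
    ns <- vapply(groups, length, 0L)
    route <- routing[[param]]
    if (route == "omnibus") {
      omni <- omnibus_compare(groups)
      ve <- variance_equal(groups)
      ph <- posthoc_compare(groups, equal_variance = ve$equal, labels = lv)
      ph$p_adjusted <- ph$p  # LSD/T3 are reported unadjusted beyond their own construction
      test_name <- omni$test
      omnibus_p <- omni$p
      posthoc_name <- if (ve$equal) "LSD" else "DunnettT3"
      min_p <- min(ph$p)
      details[[param]] <- list(route = route, omnibus = omni,
                               variance = ve, pairwise = ph)
    } else {
      pairs <- utils::combn(length(lv), 2)
      m <- ncol(pairs)
      ph <- do.call(rbind, lapply(seq_len(m), function(j) {
        i1 <- pairs[1, j]; i2 <- pairs[2, j]
        mw <- mann_whitney_u(groups[[i1]], groups[[i2]])
        data.frame(group1 = lv[i1], group2 = lv[i2],
                   mean_diff = means[i1] - means[i2],
                   U = mw$U, p = mw$p, method = "MWU")
      }))
      ph$p_adjusted <- bonferroni_adjust(ph$p, m)
      test_name <- "mann-whitney"
      omnibus_p <- NA_real_
      posthoc_name <- "MWU+Bonferroni"
      min_p <- min(ph$p_adjusted)
      details[[param]] <- list(route = route, pairwise = ph)
    }
    row <- data.frame(parameter = param)
    for (g in lv) {
      row[[paste0(g, "_mean")]] <- means[[g]]
      row[[paste0(g, "_sd")]] <- sds[[g]]
      row[[paste0(g, "_n")]] <- ns[[g]]
    }
    row$test <- test_name
    row$omnibus_p <- omnibus_p
    row$posthoc <- posthoc_name
    row$min_p <- min_p
    rows[[param]] <- row
  }
  structure(list(table = do.call(rbind, rows), details = details,
                 groups = lv),
            class = "gait_report")
}

#' @export
print.gait_report <- function(x, ...) {
  cat(sprintf("<gait_report> groups: %s\n", paste(x$groups, collapse = ", ")))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a group report to CSV and/or JSON
#'
#' @param report A [build_report()] result.
#' @param csv,json Output paths (either may be `NULL`).
#' @return The report, invisibly.
#' @export
write_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) {
    utils::write.csv(report$table, csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    payload <- list(table = report$table,
                    pairwise = lapply(report$details, `[[`, "pairwise"))
    jsonlite::write_json(payload, json, dataframe = "rows",
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  invisible(report)
}
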
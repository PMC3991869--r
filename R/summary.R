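.cycle_param_cols <- c("stride_time", "swing_time", "stance_time",
                       "stance_ratio", "max_nav", "min_nav",
                       "up_slope", "down_slope")

# per-leg aggregate of a cycles data frame
.summarize_leg <- function(cycles, leg, corridor_length, peak_times) {
  .vg_check(!is.null(cycles) && nrow(cycles) >= 3L,
            sprintf("summarize_walk: need at least 3 valid cycles for the %s leg", leg))
  means <- vapply(.cycle_param_cols, function(c) mean(cycles[[c]]), 0)
  sds <- vapply(.cycle_param_cols, function(c) stats::sd(cycles[[c]]), 0)
  duration <- max(cycles$t_heelstrike) - min(cycles$t_toeoff)
  # event timing measured relative to each cycle's mid-swing peak
  rel_toeoff <- cycles$t_toeoff - cycles$t_midswing
  rel_heelstrike <- cycles$t_heelstrike - cycles$t_midswing
  structure(
    list(leg = leg,
         mean = means, sd = sds,
         n_strides = nrow(cycles),
         gait_velocity = corridor_length / duration,
         walk_duration = duration,
         var_toeoff_time = stats::var(rel_toeoff),
         var_heelstrike_time = stats::var(rel_heelstrike),
         peak_times = peak_times),
    class = "walk_summary")
}

#' Summarize a bilateral walk
#'
#' Per-leg aggregates over the detected gait cycles: mean and SD of every
#' cycle parameter, the number of valid strides, the gait velocity (corridor
#' length divided by the first-toe-off-to-last-heel-strike duration), and the
#' variances of the toe-off and heel-strike times measured relative to each
#' cycle's mid-swing peak (irregular gait initiation inflates the toe-off
#' variance).
#'
#' @param recording A [walk_recording()] (supplies the corridor length).
#' @param cycles_left,cycles_right Results of [detect_gait_cycles()] for each
#'   leg (or bare cycle data frames).
#' @return A list with elements `left` and `right`, each a `walk_summary`.
#' @export
summarize_walk <- function(recording, cycles_left, cycles_right) {
  .vg_check(inherits(recording, "walk_recording"),
            "summarize_walk: recording must be a walk_recording")
  get_cycles <- function(x) if (is.list(x) && !is.data.frame(x)) x$cycles else x
  get_peaks <- function(x) if (is.list(x) && !is.data.frame(x)) x$peak_times else NULL
  list(
    left = .summarize_leg(get_cycles(cycles_left), "left",
                          recording$corridor_length, get_peaks(cycles_left)),
    right = .summarize_leg(get_cycles(cycles_right), "right",
                           recording$corridor_length, get_peaks(cycles_right)))
}

#' @export
print.walk_summary <- function(x, ...) {
  cat(sprintf("<walk_summary> %s leg: %d strides, velocity %.2f m/s\n",
              x$leg, x$n_strides, x$gait_velocity))
  cat(sprintf("  stride %.3f +/- %.3f s | stance ratio %.1f%% | max NAV %.1f | min NAV %.1f deg/s\n",
              x$mean["stride_time"], x$sd["stride_time"],
              x$mean["stance_ratio"], x$mean["max_nav"], x$mean["min_nav"]))
  invisible(x)
}

#' Flatten a walk summary to a one-row data frame
#'
#' Convenience used when assembling per-subject tables for group comparison.
#'
#' @param summary A `walk_summary`.
#' @return A one-row data frame with the parameter means, `n_strides`,
#'   `gait_velocity`, the event-timing variances and `leg`.
#' @export
summary_row <- function(summary) {
  out <- as.data.frame(as.list(summary$mean))
  out$n_strides <- summary$n_strides
  out$gait_velocity <- summary$gait_velocity
  out$var_toeoff_time <- summary$var_toeoff_time
  out$var_heelstrike_time <- summary$var_heelstrike_time
  out$leg <- summary$leg
  out
}
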
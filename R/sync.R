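#' Detect the synchronization spike in a recording
#'
#' Sensors are synchronized by shaking them together before the walk, which
#' induces a sudden change in angular velocity on every axis. The start time
#' is the first sample at which the largest absolute sample-to-sample change
#' across the three axes exceeds `jerk_threshold`. The default threshold sits
#' far above walking-induced inter-sample changes at 50 Hz (at most a few
#' tens of deg/s) but well below a deliberate shake.
#'
#' @param series An [angvel_series()].
#' @param jerk_threshold Threshold on the per-sample change, deg/s per sample
#'   (default 150).
#' @return The sync time `t0` in seconds.
#' @export
detect_sync_start <- function(series, jerk_threshold = 150) {
  .vg_check(inherits(series, "angvel_series"),
            "detect_sync_start: series must be an angvel_series")
  jump <- pmax(abs(diff(series$gx)), abs(diff(series$gy)), abs(diff(series$gz)))
  idx <- which(jump > jerk_threshold)
  .vg_check(length(idx) > 0L,
            sprintf("detect_sync_start: no sample-to-sample change exceeds %g deg/s (sync not found)",
                    jerk_threshold))
  series$time[idx[1] + 1L]
}

#' Estimate stationary zero offsets
#'
#' Averages each axis over a window in which the sensor is known to be
#' stationary (typically the lead-in before the sync spike), yielding the
#' per-axis zero-angular-velocity reference used for offset correction. The
#' window must be at least 1 s long and actually stationary: each axis' SD
#' over the window must be below 10 deg/s (walking motion exceeds this by an
#' order of magnitude).
#'
#' @param series An [angvel_series()].
#' @param window Numeric length-2 `(t_start, t_end)` in the series' time
#'   coordinates.
#' @param max_sd Stationarity bound on the per-axis SD, deg/s (default 10).
#' @return Named numeric vector `c(ox, oy, oz)` in deg/s.
#' @export
estimate_offsets <- function(series, window, max_sd = 10) {
  .vg_check(inherits(series, "angvel_series"),
            "estimate_offsets: series must be an angvel_series")
  .vg_check(is.numeric(window) && length(window) == 2L && window[2] > window[1],
            "estimate_offsets: window must be (t_start, t_end)")
  .vg_check(window[2] - window[1] >= 1,
            "estimate_offsets: window must span at least 1 s")
  .vg_check(window[1] >= series$time[1] - 1e-9 &&
              window[2] <= series$time[length(series$time)] + 1e-9,
            "estimate_offsets: window outside the recording")
  sel <- series$time >= window[1] & series$time <= window[2]
  sds <- c(stats::sd(series$gx[sel]), stats::sd(series$gy[sel]),
           stats::sd(series$gz[sel]))
  .vg_check(all(sds < max_sd),
            sprintf("estimate_offsets: window not stationary (per-axis SD %.1f/%.1f/%.1f deg/s, limit %g)",
                    sds[1], sds[2], sds[3], max_sd))
  c(ox = mean(series$gx[sel]), oy = mean(series$gy[sel]),
    oz = mean(series$gz[sel]))
}

# shift a series so that its sync time maps to t = 0
.shift_series <- function(series, t0) {
  angvel_series(series$time - t0, series$gx, series$gy, series$gz,
                leg = series$leg, sensor_id = series$sensor_id)
}

# crop a series to [t_min, t_max]
.crop_series <- function(series, t_min, t_max) {
  sel <- series$time >= t_min - 1e-9 & series$time <= t_max + 1e-9
  angvel_series(series$time[sel], series$gx[sel], series$gy[sel],
                series$gz[sel], leg = series$leg, sensor_id = series$sensor_id)
}

#' Align a sensor pair on their synchronization spikes
#'
#' Shifts both legs' recordings so their sync spikes map to `t = 0` and trims
#' them to the overlapping time span, yielding a bilateral recording on a
#' common clock.
#'
#' @param left,right `angvel_series` objects (left/right leg).
#' @param jerk_threshold Passed to [detect_sync_start()].
#' @param group,lesion_side,corridor_length,subject_meta Metadata attached to
#'   the resulting [walk_recording()].
#' @return A [walk_recording()].
#' @export
align_pair <- function(left, right, jerk_threshold = 150,
                       group = "control", lesion_side = "none",
                       corridor_length = 88.8, subject_meta = list()) {
  t0_l <- detect_sync_start(left, jerk_threshold)
  t0_r <- detect_sync_start(right, jerk_threshold)
  truth_l <- attr(left, "truth"); truth_r <- attr(right, "truth")
  left <- .shift_series(left, t0_l)
  right <- .shift_series(right, t0_r)
  t_min <- max(left$time[1], right$time[1])
  t_max <- min(left$time[length(left$time)], right$time[length(right$time)])
  .vg_check(t_max - t_min > 0, "align_pair: recordings do not overlap")
  left <- .crop_series(left, t_min, t_max)
  right <- .crop_series(right, t_min, t_max)
  shift_truth <- function(truth, t0) {
    if (is.null(truth)) return(NULL)
    for (f in c("sync_time", "walk_start", "cycle_starts", "t_toeoff",
                "t_midswing", "t_heelstrike")) truth[[f]] <- truth[[f]] - t0
    truth
  }
  attr(left, "truth") <- shift_truth(truth_l, t0_l)
  attr(right, "truth") <- shift_truth(truth_r, t0_r)
  walk_recording(left, right, group = group, lesion_side = lesion_side,
                 corridor_length = corridor_length,
                 subject_meta = subject_meta)
}
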
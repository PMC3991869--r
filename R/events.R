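# indices of strict-ish local maxima (greater than left neighbour,
# not less than right neighbour)
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

.local_minima <- function(x) .local_maxima(-x)

# topographic prominence of the peak at index i: height above the higher of
# the two key saddles, reaching outward to the next higher sample on each
# side; a segment boundary acts as a col (so low-amplitude bumps near the
# edges are not inflated by one-sided deep troughs)
.prominence <- function(x, i) {
  n <- length(x)
  lmin <- x[i]
  j <- i - 1L
  while (j >= 1L) {
    if (x[j] > x[i]) break
    if (x[j] < lmin) lmin <- x[j]
    j <- j - 1L
  }
  rmin <- x[i]
  j <- i + 1L
  while (j <= n) {
    if (x[j] > x[i]) break
    if (x[j] < rmin) rmin <- x[j]
    j <- j + 1L
  }
  x[i] - max(lmin, rmin)
}

#' Detect mid-swing peaks in the pitch signal
#'
#' The mid-swing phase produces the dominant positive peak of each stride on
#' the shank pitch channel. Peaks are local maxima whose topographic
#' prominence is at least `prominence_frac` times the 90th percentile of the
#' positive signal values, separated by at least `min_separation` seconds
#' (taller peaks win ties).
#'
#' @param nav A [pitch_nav()] series.
#' @param min_separation Minimum peak separation in seconds (default 0.5, a
#'   little over the shortest physiological stride at comfortable speed).
#' @param prominence_frac Prominence threshold as a fraction of the 90th
#'   percentile of positive signal values (default 0.4).
#' @param segment Optional `(t0, t1)` restricting the search (use it to skip
#'   the sync transient).
#' @return Numeric vector of peak times, in time order; errors if fewer than
#'   3 qualify.
#' @export
detect_midswing_peaks <- function(nav, min_separation = 0.5,
                                  prominence_frac = 0.4, segment = NULL) {
  .vg_check(inherits(nav, "nav_series"),
            "detect_midswing_peaks: nav must be a nav_series")
  sel <- rep(TRUE, length(nav$time))
  if (!is.null(segment)) sel <- nav$time >= segment[1] & nav$time <= segment[2]
  tt <- nav$time[sel]; x <- nav$nav[sel]
  .vg_check(length(tt) >= 2L && (tt[length(tt)] - tt[1]) >= 3,
            "detect_midswing_peaks: walking segment must span at least 3 s")
  pos <- x[x > 0]
  if (length(pos) < 10L) .vg_stop("detect_midswing_peaks: too few strides (no positive signal)")
  thr <- prominence_frac * stats::quantile(pos, 0.9, names = FALSE)
  cand <- .local_maxima(x)
  # a mid-swing peak must both stand tall (height) and stand alone
  # (prominence): low noise bumps on the mid-stance plateau can be
  # topographically prominent between two deep troughs, so height alone
  # filters them while prominence rejects shoulders of real peaks
  cand <- cand[x[cand] >= thr]
  if (length(cand)) {
    prom <- vapply(cand, function(i) .prominence(x, i), 0)
    cand <- cand[prom >= thr]
  }
  # enforce separation, keeping taller peaks
  keep <- integer(0)
  for (i in cand[order(x[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(tt[i] - tt[keep]) > min_separation)) {
      keep <- c(keep, i)
    }
  }
  keep <- sort(keep)
  .vg_check(length(keep) >= 3L,
            sprintf("detect_midswing_peaks: too few strides (%d peaks found, need >= 3)",
                    length(keep)))
  tt[keep]
}

.idx_range <- function(time, t0, t1) which(time > t0 & time < t1)

#' Detect the four gait events of one stride
#'
#' Around one detected mid-swing peak: the toe-off trough is the signal
#' minimum between the midpoint to the previous peak and the peak (the global
#' cycle minimum); the heel strike is the first prominent local minimum after
#' the peak and before the midpoint to the next peak; the mid-stance point is
#' where `|signal|` is smallest between heel strike and the following
#' toe-off (or, if unknown, the remainder of the inter-peak window). Event
#' amplitudes are read from the signal at the detected times.
#'
#' @param nav A [pitch_nav()] series.
#' @param peak_time A detected mid-swing peak time.
#' @param prev_peak_time,next_peak_time Neighbouring peak times, or `NA` to
#'   use the recording bounds.
#' @param next_toeoff_time Optional next cycle's toe-off time bounding the
#'   mid-stance search.
#' @return A list of class `gait_events` with fields `t_toeoff`,
#'   `t_midswing`, `t_heelstrike`, `t_midstance`, the corresponding `v_*`
#'   amplitudes, `valid`, and `reason` (non-`NULL` when invalid).
#' @export
detect_cycle_events <- function(nav, peak_time, prev_peak_time = NA,
                                next_peak_time = NA, next_toeoff_time = NULL) {
  tt <- nav$time; x <- nav$nav
  t_start <- tt[1]; t_end <- tt[length(tt)]
  lo <- if (is.na(prev_peak_time)) t_start else (prev_peak_time + peak_time) / 2
  hi <- if (is.na(next_peak_time)) t_end else (peak_time + next_peak_time) / 2

  fail <- function(reason) {
    structure(list(valid = FALSE, reason = reason), class = "gait_events")
  }

  ip <- which.min(abs(tt - peak_time))
  # toe-off: minimum in (lo, peak)
  win <- .idx_range(tt, lo, peak_time)
  if (!length(win)) return(fail("empty toe-off window"))
  ie <- win[which.min(x[win])]

  # heel strike: first prominent local minimum in (peak, hi)
  win <- .idx_range(tt, peak_time, hi)
  if (length(win) < 3L) return(fail("empty heel-strike window"))
  seg <- x[win]
  mins <- .local_minima(seg)
  if (!length(mins)) return(fail("no local minimum after mid-swing peak"))
  depth_ok <- seg[mins] <= min(seg) + 0.15 * (x[ip] - min(seg))
  mins <- mins[depth_ok]
  if (!length(mins)) return(fail("no prominent heel-strike trough"))
  ig <- win[mins[1]]

  # mid-stance: minimum |signal| between heel strike and the next toe-off
  hi_ms <- if (!is.null(next_toeoff_time)) next_toeoff_time else hi
  win <- .idx_range(tt, tt[ig], hi_ms)
  if (!length(win)) return(fail("empty mid-stance window"))
  ih <- win[which.min(abs(x[win]))]

  ev <- structure(
    list(t_toeoff = tt[ie], t_midswing = tt[ip], t_heelstrike = tt[ig],
         t_midstance = tt[ih],
         v_toeoff = x[ie], v_midswing = x[ip], v_heelstrike = x[ig],
         v_midstance = x[ih], valid = TRUE, reason = NULL),
    class = "gait_events")
  if (!(ev$t_toeoff < ev$t_midswing && ev$t_midswing < ev$t_heelstrike &&
        ev$t_heelstrike < ev$t_midstance)) {
    ev$valid <- FALSE; ev$reason <- "event times out of order"
  } else if (!(ev$v_toeoff <= ev$v_heelstrike)) {
    ev$valid <- FALSE
    ev$reason <- "toe-off trough is not the cycle minimum"
  } else if (!(ev$v_heelstrike < ev$v_midswing)) {
    ev$valid <- FALSE; ev$reason <- "heel-strike above mid-swing peak"
  }
  ev
}

#' Gait parameters of one stride from consecutive event sets
#'
#' Stride time is toe-off to next toe-off; stance time is heel strike to the
#' next toe-off; swing is their difference. The up-slope is the secant from
#' the toe-off trough to the mid-swing peak, the down-slope the secant from
#' the peak to the heel-strike trough.
#'
#' @param events,events_next `gait_events` of consecutive strides.
#' @return A one-row data frame (class also `gait_cycle`) with the event
#'   times/values and `stride_time`, `swing_time`, `stance_time`,
#'   `stance_ratio` (%), `max_nav`, `min_nav`, `up_slope`, `down_slope`; or
#'   `NULL` if either event set is invalid or a duration is non-positive.
#' @export
compute_cycle <- function(events, events_next) {
  if (!isTRUE(events$valid) || !isTRUE(events_next$valid)) return(NULL)
  stride <- events_next$t_toeoff - events$t_toeoff
  stance <- events_next$t_toeoff - events$t_heelstrike
  swing <- stride - stance
  if (stride <= 0 || stance <= 0 || swing <= 0) return(NULL)
  up <- (events$v_midswing - events$v_toeoff) /
    (events$t_midswing - events$t_toeoff)
  down <- (events$v_heelstrike - events$v_midswing) /
    (events$t_heelstrike - events$t_midswing)
  out <- data.frame(
    t_toeoff = events$t_toeoff, t_midswing = events$t_midswing,
    t_heelstrike = events$t_heelstrike, t_midstance = events$t_midstance,
    stride_time = stride, swing_time = swing, stance_time = stance,
    stance_ratio = 100 * stance / stride,
    max_nav = events$v_midswing, min_nav = events$v_toeoff,
    up_slope = up, down_slope = down)
  class(out) <- c("gait_cycle", class(out))
  out
}

#' Detect and parameterize all gait cycles of a walk
#'
#' Runs peak detection, per-cycle event detection and cycle parameterization
#' over a pitch signal. Cycles failing event detection are skipped (counted,
#' with reasons) rather than imputed.
#'
#' @param nav A [pitch_nav()] series.
#' @inheritParams detect_midswing_peaks
#' @return A list with `cycles` (data frame, one row per valid cycle),
#'   `peak_times`, `n_skipped` and `skip_reasons`.
#' @export
detect_gait_cycles <- function(nav, min_separation = 0.5,
                               prominence_frac = 0.4, segment = NULL) {
  peaks <- detect_midswing_peaks(nav, min_separation, prominence_frac, segment)
  np <- length(peaks)
  events <- vector("list", np)
  for (i in seq_len(np)) {
    events[[i]] <- detect_cycle_events(
      nav, peaks[i],
      prev_peak_time = if (i > 1L) peaks[i - 1L] else NA,
      next_peak_time = if (i < np) peaks[i + 1L] else NA)
  }
  # refine mid-stance windows now that the next toe-off is known
  for (i in seq_len(np - 1L)) {
    if (isTRUE(events[[i]]$valid) && isTRUE(events[[i + 1L]]$valid)) {
      events[[i]] <- detect_cycle_events(
        nav, peaks[i],
        prev_peak_time = if (i > 1L) peaks[i - 1L] else NA,
        next_peak_time = peaks[i + 1L],
        next_toeoff_time = events[[i + 1L]]$t_toeoff)
    }
  }
  rows <- list(); skipped <- character(0)
  for (i in seq_len(np - 1L)) {
    cyc <- compute_cycle(events[[i]], events[[i + 1L]])
    if (is.null(cyc)) {
      reason <- events[[i]]$reason %||% events[[i + 1L]]$reason %||%
        "non-positive duration"
      skipped <- c(skipped, sprintf("cycle %d: %s", i, reason))
    } else {
      rows[[length(rows) + 1L]] <- cyc
    }
  }
  cycles <- if (length(rows)) do.call(rbind, rows) else NULL
  if (length(skipped)) {
    message(sprintf("detect_gait_cycles: skipped %d cycle(s)", length(skipped)))
  }
  list(cycles = cycles, peak_times = peaks,
       n_skipped = length(skipped), skip_reasons = skipped)
}

#' Time-normalized cycle ensemble
#'
#' Resamples every toe-off-to-toe-off cycle onto a common normalized stride
#' axis and returns the pointwise mean and SD — the classic gait-cycle
#' ensemble average.
#'
#' @param nav A [pitch_nav()] series.
#' @param starts Toe-off times delimiting the cycles (length >= 4, i.e. at
#'   least 3 cycles).
#' @param n_points Number of points on the normalized stride (default 101).
#' @return A list with `phase` (0..1), `mean`, `sd` and `n_cycles`.
#' @export
cycle_ensemble <- function(nav, starts, n_points = 101L) {
  .vg_check(length(starts) >= 4L,
            "cycle_ensemble: need at least 3 cycles (4 toe-off times)")
  starts <- sort(starts)
  phase <- seq(0, 1, length.out = n_points)
  mat <- matrix(NA_real_, nrow = length(starts) - 1L, ncol = n_points)
  for (i in seq_len(length(starts) - 1L)) {
    t0 <- starts[i]; t1 <- starts[i + 1L]
    sel <- nav$time >= t0 - 1e-9 & nav$time <= t1 + 1e-9
    mat[i, ] <- stats::approx(
      (nav$time[sel] - t0) / (t1 - t0), nav$nav[sel], xout = phase,
      rule = 2)$y
  }
  list(phase = phase, mean = colMeans(mat), sd = apply(mat, 2L, stats::sd),
       n_cycles = nrow(mat))
}
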
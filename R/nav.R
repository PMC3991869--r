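#' Per-axis share of the total angular-velocity magnitude
#'
#' For each sample, computes the share of each axis in the total absolute
#' angular velocity after offset correction:
#' `share_a = |g_a - o_a| / sum_axes |g_axis - o_axis|`.
#' Absolute deviations from the stationary zero are used so the shares are
#' bounded in `[0, 1]` and sum to one; samples whose denominator falls below
#' `epsilon` correspond to an effectively stationary shank and are returned
#' as missing.
#'
#' @param series An [angvel_series()].
#' @param offsets Named or positional numeric vector `(ox, oy, oz)` from
#'   [estimate_offsets()].
#' @param epsilon Denominator threshold in deg/s below which shares are
#'   undefined (default 1).
#' @return A data frame with `time`, `share_x`, `share_y`, `share_z` (`NA`
#'   where undefined).
#' @export
axis_share <- function(series, offsets = c(0, 0, 0), epsilon = 1) {
  .vg_check(inherits(series, "angvel_series"),
            "axis_share: series must be an angvel_series")
  .vg_check(is.numeric(offsets) && length(offsets) == 3L,
            "axis_share: offsets must be length-3 numeric")
  ax <- abs(series$gx - offsets[1])
  ay <- abs(series$gy - offsets[2])
  az <- abs(series$gz - offsets[3])
  denom <- ax + ay + az
  ok <- denom >= epsilon
  out <- data.frame(time = series$time,
                    share_x = ifelse(ok, ax / denom, NA_real_),
                    share_y = ifelse(ok, ay / denom, NA_real_),
                    share_z = ifelse(ok, az / denom, NA_real_))
  out
}

#' Median per-axis share over a segment
#'
#' Walk-level summary of the axial analysis: the median share of each axis
#' over the (defined) samples of the walking segment.
#'
#' @param shares Output of [axis_share()].
#' @param segment Optional `(t0, t1)` restricting the samples used.
#' @return Named numeric vector `c(share_x, share_y, share_z)`.
#' @export
median_axis_share <- function(shares, segment = NULL) {
  sel <- rep(TRUE, nrow(shares))
  if (!is.null(segment)) {
    sel <- shares$time >= segment[1] & shares$time <= segment[2]
  }
  c(share_x = stats::median(shares$share_x[sel], na.rm = TRUE),
    share_y = stats::median(shares$share_y[sel], na.rm = TRUE),
    share_z = stats::median(shares$share_z[sel], na.rm = TRUE))
}

#' Offset-corrected pitch angular velocity
#'
#' The gait-parameter signal: the pitch (z-axis) channel minus its stationary
#' zero offset, in deg/s. No sign flip is applied between legs, since all
#' sensors are mounted with their axes aligned in the same physical
#' direction; `reference_leg` only records which leg downstream presentation
#' is anchored to.
#'
#' @param series An [angvel_series()].
#' @param offsets Numeric `(ox, oy, oz)` from [estimate_offsets()].
#' @param reference_leg `"left"` (default) or `"right"`.
#' @param shares If `TRUE` (default), also compute [axis_share()] channels.
#' @return An object of class `nav_series`: list with `time`, `nav`
#'   (deg/s), optional `shares` data frame, `leg`, `dt`.
#' @export
pitch_nav <- function(series, offsets = c(0, 0, 0),
                      reference_leg = c("left", "right"), shares = TRUE) {
  reference_leg <- match.arg(reference_leg)
  .vg_check(inherits(series, "angvel_series"),
            "pitch_nav: series must be an angvel_series")
  .vg_check(is.numeric(offsets) && length(offsets) == 3L,
            "pitch_nav: offsets must be length-3 numeric")
  out <- structure(
    list(time = series$time, nav = series$gz - offsets[3],
         shares = if (shares) axis_share(series, offsets) else NULL,
         leg = series$leg, reference_leg = reference_leg, dt = series$dt),
    class = "nav_series")
  attr(out, "truth") <- attr(series, "truth")
  out
}

#' @export
print.nav_series <- function(x, ...) {
  cat(sprintf("<nav_series> %s leg, %d samples, nav range [%.1f, %.1f] deg/s\n",
              x$leg, length(x$time), min(x$nav), max(x$nav)))
  invisible(x)
}
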
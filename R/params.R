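#' Per-stride cycle template parameters
#'
#' Bundles the quantities that define one idealized stride of the shank pitch
#' angular-velocity waveform: the three event amplitudes (toe-off trough,
#' mid-swing peak, heel-strike trough), the two swing-phase slopes, and the
#' stride/swing/stance durations. The toe-off trough is the global minimum of
#' the cycle and the mid-swing peak its global maximum; the heel-strike trough
#' is a shallower local minimum between mid-swing and the stance plateau.
#'
#' @param stride_time Stride duration (toe-off to next toe-off), seconds.
#' @param swing_time Swing duration (toe-off to heel strike), seconds.
#' @param stance_time Stance duration (heel strike to next toe-off), seconds.
#'   Must equal `stride_time - swing_time` within 1e-9 s.
#' @param a_toeoff Toe-off trough amplitude, deg/s (negative; cycle minimum).
#' @param a_midswing Mid-swing peak amplitude, deg/s (positive; cycle maximum).
#' @param a_heelstrike Heel-strike trough amplitude, deg/s (negative, shallower
#'   than the toe-off trough). Defaults to `0.85 * a_toeoff`.
#' @param up_slope Slope of the toe-off to mid-swing rise, deg/s^2 (positive).
#' @param down_slope Slope of the descent leaving the mid-swing peak,
#'   deg/s^2 (negative).
#'
#' @return An object of class `cycle_params` (a named list of the eight
#'   fields).
#' @seealso [default_params()], [make_cycle_template()]
#' @export
cycle_params <- function(stride_time, swing_time, stance_time,
                         a_toeoff, a_midswing,
                         a_heelstrike = 0.85 * a_toeoff,
                         up_slope, down_slope) {
  p <- structure(
    list(stride_time = stride_time, swing_time = swing_time,
         stance_time = stance_time, a_toeoff = a_toeoff,
         a_midswing = a_midswing, a_heelstrike = a_heelstrike,
         up_slope = up_slope, down_slope = down_slope),
    class = "cycle_params")
  validate_cycle_params(p)
  p
}

#' Validate cycle parameters
#'
#' Checks the internal consistency of a [cycle_params()] object: the duration
#' identity `stride = swing + stance`, the amplitude ordering
#' `a_toeoff < a_heelstrike < 0 < a_midswing`, slope signs, and that each
#' slope-implied swing segment fits inside the swing phase.
#'
#' @param p A `cycle_params` object.
#' @return `p`, invisibly; errors name the violated constraint.
#' @export
validate_cycle_params <- function(p) {
  for (f in c("stride_time", "swing_time", "stance_time", "a_toeoff",
              "a_midswing", "a_heelstrike", "up_slope", "down_slope")) {
    .vg_check(.is_scalar_num(p[[f]]),
              sprintf("cycle_params: field '%s' must be a finite number", f))
  }
  .vg_check(p$stride_time > 0 && p$swing_time > 0 && p$stance_time > 0,
            "cycle_params: durations must be positive")
  .vg_check(abs(p$stride_time - (p$swing_time + p$stance_time)) <= 1e-9,
            "cycle_params: stride_time must equal swing_time + stance_time (within 1e-9 s)")
  .vg_check(p$a_toeoff < p$a_heelstrike,
            "cycle_params: a_toeoff must be below a_heelstrike (toe-off is the cycle minimum)")
  .vg_check(p$a_heelstrike < 0,
            "cycle_params: a_heelstrike must be negative")
  .vg_check(p$a_midswing > 0,
            "cycle_params: a_midswing must be positive")
  .vg_check(p$up_slope > 0, "cycle_params: up_slope must be positive")
  .vg_check(p$down_slope < 0, "cycle_params: down_slope must be negative")
  d_up <- (p$a_midswing - p$a_toeoff) / p$up_slope
  d_down <- (p$a_heelstrike - p$a_midswing) / p$down_slope
  .vg_check(d_up < p$swing_time,
            "cycle_params: up-slope segment duration must be shorter than swing_time")
  .vg_check(d_down < p$swing_time,
            "cycle_params: down-slope segment duration must be shorter than swing_time")
  invisible(p)
}

# calibration table: published group means and SDs for the eight gait
# parameters (normal controls, left- and right-lesion vestibular neuritis)
.vg_reference <- local({
  tab <- data.frame(
    parameter = c("max_nav", "min_nav", "down_slope", "up_slope",
                  "stride_time", "swing_time", "stance_time", "stance_ratio"),
    units = c("deg/s", "deg/s", "deg/s^2", "deg/s^2", "s", "s", "s", "%"),
    normal_mean = c(368.6, -172.3, -3003, 2968.7, 0.98, 0.389, 0.591, 60.4),
    normal_sd = c(42.5, 34.5, 341.7, 973.9, 0.062, 0.060, 0.044, 0.046),
    lvn_mean = c(258.6, -125.8, -2139.4, 1692.6, 1.15, 0.430, 0.722, 62.7),
    lvn_sd = c(42.3, 26.9, 401.1, 429, 0.115, 0.053, 0.083, 0.030),
    rvn_mean = c(349.6, -195, -3251.9, 1893.1, 1.12, 0.485, 0.633, 56.6),
    rvn_sd = c(51.1, 47.9, 1021.3, 144.5, 0.069, 0.046, 0.059, 0.035),
    stringsAsFactors = FALSE)
  tab
})

#' Reference gait-parameter calibration values
#'
#' The published normative values (group mean and SD per parameter) that
#' calibrate the generator presets: normal controls and left-/right-lesion
#' vestibular neuritis groups. Stance-ratio SDs are reproduced as printed in
#' the source table, where they appear to be on the fraction scale while the
#' means are percentages; they are preserved verbatim and not rescaled.
#'
#' @return A data frame with one row per parameter (`max_nav`, `min_nav`,
#'   `down_slope`, `up_slope`, `stride_time`, `swing_time`, `stance_time`,
#'   `stance_ratio`) and mean/SD columns per group.
#' @export
gait_reference_values <- function() .vg_reference

#' Verify arithmetic identities of the reference table
#'
#' Checks that the published group means satisfy the definitional identities
#' `stride_time = swing_time + stance_time` and
#' `stance_ratio = 100 * stance_time / stride_time` for every group column,
#' within the tolerance implied by the printed precision (half a unit in the
#' last printed digit, propagated through the ratio).
#'
#' @return A data frame with one row per group and identity, the computed and
#'   stated values, the propagated rounding tolerance, and a logical `ok`.
#' @export
verify_reference_identities <- function() {
  ref <- gait_reference_values()
  g <- function(param, col) ref[[col]][ref$parameter == param]
  out <- list()
  for (col in c("normal_mean", "lvn_mean", "rvn_mean")) {
    stride <- g("stride_time", col); swing <- g("swing_time", col)
    stance <- g("stance_time", col); ratio <- g("stance_ratio", col)
    grp <- sub("_mean$", "", col)
    # printed durations carry 2-3 decimals: half-unit rounding of each term
    tol_stride <- 0.005 + 0.0005 + 0.0005
    computed <- swing + stance
    out[[length(out) + 1L]] <- data.frame(
      group = grp, identity = "stride = swing + stance",
      computed = computed, stated = stride, tolerance = tol_stride,
      ok = abs(computed - stride) <= tol_stride)
    # ratio tolerance: propagate half-unit rounding of stance and stride
    tol_ratio <- ratio * (0.005 / stride + 0.0005 / stance)
    computed_r <- 100 * stance / stride
    out[[length(out) + 1L]] <- data.frame(
      group = grp, identity = "ratio = 100 * stance / stride",
      computed = computed_r, stated = ratio, tolerance = tol_ratio,
      ok = abs(computed_r - ratio) <= tol_ratio)
  }
  do.call(rbind, out)
}

#' Preset cycle parameters calibrated to published group means
#'
#' Returns the template parameters for one of the calibrated presets. The
#' `normal` column is the healthy-control preset; `lvn` and `rvn` are the
#' left- and right-lesion vestibular neuritis presets. The heel-strike trough
#' amplitude is not published and defaults to `0.85 * a_toeoff`, keeping the
#' toe-off trough the global cycle minimum. Because the published stride,
#' swing and stance means are independently rounded, the stride time is
#' adjusted by at most 0.002 s so that `stride = swing + stance` holds
#' exactly.
#'
#' @param group `"control"` or `"vn"`.
#' @param column Preset column: `"normal"` (required for control) or one of
#'   `"lvn"`, `"rvn"` for the vn group. Defaults to `"normal"` for control
#'   and `"lvn"` for vn.
#' @return A [cycle_params()] object.
#' @examples
#' default_params("control")$stride_time    # 0.98
#' default_params("vn", "lvn")$stance_time  # 0.722
#' @export
default_params <- function(group = c("control", "vn"), column = NULL) {
  group <- match.arg(group)
  if (is.null(column)) column <- if (group == "control") "normal" else "lvn"
  column <- match.arg(column, c("normal", "lvn", "rvn"))
  if (group == "control") {
    .vg_check(column == "normal",
              "default_params: group 'control' only has the 'normal' column")
  } else {
    .vg_check(column %in% c("lvn", "rvn"),
              "default_params: group 'vn' requires column 'lvn' or 'rvn'")
  }
  ref <- gait_reference_values()
  mcol <- paste0(column, "_mean")
  g <- function(param) ref[[mcol]][ref$parameter == param]
  swing <- g("swing_time"); stance <- g("stance_time")
  cycle_params(
    stride_time = swing + stance,  # printed stride differs by <= 0.002 s
    swing_time = swing,
    stance_time = stance,
    a_toeoff = g("min_nav"),
    a_midswing = g("max_nav"),
    up_slope = g("up_slope"),
    down_slope = g("down_slope"))
}

#' Interpolate between two cycle-parameter sets
#'
#' Field-wise linear interpolation, used for the contralateral (non-lesion)
#' leg of a vestibular-neuritis walk, for which no published template exists.
#' The duration identity is re-enforced after interpolation.
#'
#' @param p,q `cycle_params` objects.
#' @param weight Weight on `p` (`weight = 1` returns `p`). Default 0.5.
#' @return A `cycle_params` object.
#' @export
interpolate_params <- function(p, q, weight = 0.5) {
  .vg_check(.is_scalar_num(weight) && weight >= 0 && weight <= 1,
            "interpolate_params: weight must be in [0, 1]")
  mix <- function(f) weight * p[[f]] + (1 - weight) * q[[f]]
  swing <- mix("swing_time"); stance <- mix("stance_time")
  cycle_params(
    stride_time = swing + stance, swing_time = swing, stance_time = stance,
    a_toeoff = mix("a_toeoff"), a_midswing = mix("a_midswing"),
    a_heelstrike = mix("a_heelstrike"),
    up_slope = mix("up_slope"), down_slope = mix("down_slope"))
}

#' Rescale the durations of a cycle-parameter set
#'
#' Multiplies stride, swing and stance by a common factor while leaving
#' amplitudes and the up/down slopes' amplitude span unchanged. Useful to set
#' a target cadence (e.g. a stride interval of `1 / f1`) while keeping the
#' waveform shape.
#'
#' @param p A `cycle_params` object.
#' @param stride_time New stride duration in seconds.
#' @return A `cycle_params` object with scaled durations and slopes rescaled
#'   by the inverse factor (so segment durations scale with the stride).
#' @export
set_stride_time <- function(p, stride_time) {
  .vg_check(.is_scalar_num(stride_time) && stride_time > 0,
            "set_stride_time: stride_time must be positive")
  s <- stride_time / p$stride_time
  cycle_params(
    stride_time = p$stride_time * s, swing_time = p$swing_time * s,
    stance_time = p$stance_time * s,
    a_toeoff = p$a_toeoff, a_midswing = p$a_midswing,
    a_heelstrike = p$a_heelstrike,
    up_slope = p$up_slope / s, down_slope = p$down_slope / s)
}

#' @export
print.cycle_params <- function(x, ...) {
  cat("<cycle_params>\n")
  cat(sprintf("  stride %.3f s = swing %.3f s + stance %.3f s\n",
              x$stride_time, x$swing_time, x$stance_time))
  cat(sprintf("  amplitudes (deg/s): toe-off %.1f, mid-swing %.1f, heel-strike %.1f\n",
              x$a_toeoff, x$a_midswing, x$a_heelstrike))
  cat(sprintf("  slopes (deg/s^2): up %.1f, down %.1f\n",
              x$up_slope, x$down_slope))
  invisible(x)
}
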
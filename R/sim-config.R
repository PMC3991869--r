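#' Simulation configuration for synthetic walks
#'
#' Collects every knob of the synthetic bilateral shank-gyroscope walk
#' generator. Defaults describe a healthy control walking a one-way 88.8 m
#' corridor at normal speed with mild stride-to-stride variability; the `vn`
#' group preset slows the walk and swaps the lesion-side leg to the matching
#' vestibular-neuritis template (the contralateral leg uses a 50/50
#' interpolation toward the control template, as no contralateral template is
#' published).
#'
#' @param group `"control"` or `"vn"`.
#' @param lesion_side `"left"`, `"right"` or `"none"`. Required (non-none) for
#'   the vn group; must be `"none"` for controls.
#' @param left_params,right_params `cycle_params` for each leg; defaults are
#'   derived from `group`/`lesion_side` presets.
#' @param stride_time_cv Coefficient of variation of per-cycle durations
#'   (log-normal multiplicative jitter), in `[0, 0.5)`. Default 0.03, a
#'   typical stride-to-stride CV for steady adult gait.
#' @param amplitude_cv Coefficient of variation of per-cycle amplitudes.
#'   Default 0.05.
#' @param noise_sd SD of additive white Gaussian sensor noise, deg/s.
#'   Default 5.
#' @param roll_yaw_fraction Amplitude of the roll (x) and yaw (y) channels
#'   relative to the pitch channel. Default 0.3, so pitch dominates as it does
#'   on a shank during straight walking.
#' @param corridor_length Corridor length in metres. Default 88.8.
#' @param walking_speed Mean walking speed in m/s. Default 1.11 for controls,
#'   0.84 for the vn group.
#' @param stationary_lead Duration of the stationary segments before the sync
#'   spike and after the walk, seconds. Default 5.
#' @param stationary_offset Constant per-axis zero offsets (deg/s) applied to
#'   the whole recording, emulating gyroscope bias; default `c(2, -3, 1.5)`.
#' @param sync_spike_amplitude Amplitude of the 2-sample synchronization
#'   spike, deg/s. Default 500.
#' @param sample_interval Sampling interval in seconds. Default 0.02 (50 Hz).
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(group = c("control", "vn"),
                       lesion_side = c("none", "left", "right"),
                       left_params = NULL, right_params = NULL,
                       stride_time_cv = 0.03, amplitude_cv = 0.05,
                       noise_sd = 5, roll_yaw_fraction = 0.3,
                       corridor_length = 88.8, walking_speed = NULL,
                       stationary_lead = 5,
                       stationary_offset = c(2, -3, 1.5),
                       sync_spike_amplitude = 500,
                       sample_interval = 0.02, seed = 1L) {
  group <- match.arg(group)
  lesion_side <- match.arg(lesion_side)
  if (group == "vn") {
    .vg_check(lesion_side != "none",
              "sim_config: group 'vn' requires lesion_side 'left' or 'right'")
  }
  if (is.null(walking_speed)) {
    walking_speed <- if (group == "control") 1.11 else 0.84
  }
  if (is.null(left_params) || is.null(right_params)) {
    normal <- default_params("control", "normal")
    if (group == "control") {
      if (is.null(left_params)) left_params <- normal
      if (is.null(right_params)) right_params <- normal
    } else {
      column <- if (lesion_side == "left") "lvn" else "rvn"
      lesioned <- default_params("vn", column)
      contra <- interpolate_params(lesioned, normal, 0.5)
      if (is.null(left_params)) {
        left_params <- if (lesion_side == "left") lesioned else contra
      }
      if (is.null(right_params)) {
        right_params <- if (lesion_side == "right") lesioned else contra
      }
    }
  }
  validate_cycle_params(left_params)
  validate_cycle_params(right_params)
  .vg_check(.is_scalar_num(stride_time_cv) && stride_time_cv >= 0 && stride_time_cv < 0.5,
            "sim_config: stride_time_cv must be in [0, 0.5)")
  .vg_check(.is_scalar_num(amplitude_cv) && amplitude_cv >= 0 && amplitude_cv < 0.5,
            "sim_config: amplitude_cv must be in [0, 0.5)")
  .vg_check(.is_scalar_num(noise_sd) && noise_sd >= 0,
            "sim_config: noise_sd must be >= 0")
  .vg_check(.is_scalar_num(roll_yaw_fraction) && roll_yaw_fraction >= 0,
            "sim_config: roll_yaw_fraction must be >= 0")
  .vg_check(.is_scalar_num(corridor_length) && corridor_length > 0,
            "sim_config: corridor_length must be > 0")
  .vg_check(.is_scalar_num(walking_speed) && walking_speed > 0,
            "sim_config: walking_speed must be > 0")
  .vg_check(.is_scalar_num(stationary_lead) && stationary_lead >= 2,
            "sim_config: stationary_lead must be >= 2 s (offset-estimation window)")
  .vg_check(is.numeric(stationary_offset) && length(stationary_offset) == 3L,
            "sim_config: stationary_offset must be a length-3 numeric vector")
  .vg_check(.is_scalar_num(sync_spike_amplitude) && sync_spike_amplitude >= 0,
            "sim_config: sync_spike_amplitude must be >= 0")
  .vg_check(.is_scalar_num(sample_interval) && sample_interval > 0,
            "sim_config: sample_interval must be > 0")
  structure(
    list(group = group, lesion_side = lesion_side,
         left_params = left_params, right_params = right_params,
         stride_time_cv = stride_time_cv, amplitude_cv = amplitude_cv,
         noise_sd = noise_sd, roll_yaw_fraction = roll_yaw_fraction,
         corridor_length = corridor_length, walking_speed = walking_speed,
         stationary_lead = stationary_lead,
         stationary_offset = as.numeric(stationary_offset),
         sync_spike_amplitude = sync_spike_amplitude,
         sample_interval = sample_interval, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> group=%s lesion=%s corridor=%.1f m speed=%.2f m/s\n",
              x$group, x$lesion_side, x$corridor_length, x$walking_speed))
  cat(sprintf("  stride_cv=%.3f amp_cv=%.3f noise_sd=%.1f deg/s seed=%d\n",
              x$stride_time_cv, x$amplitude_cv, x$noise_sd, x$seed))
  invisible(x)
}
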
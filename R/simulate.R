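# scale a template's parameters by per-cycle duration and amplitude factors,
# keeping the parameter set internally consistent (slopes scale as amp/time)
.scaled_params <- function(p, f_time, f_amp) {
  cycle_params(
    stride_time = p$stride_time * f_time,
    swing_time = p$swing_time * f_time,
    stance_time = p$stance_time * f_time,
    a_toeoff = p$a_toeoff * f_amp,
    a_midswing = p$a_midswing * f_amp,
    a_heelstrike = p$a_heelstrike * f_amp,
    up_slope = p$up_slope * f_amp / f_time,
    down_slope = p$down_slope * f_amp / f_time)
}

#' Simulate one leg's gyroscope recording
#'
#' Emits a continuous 3-axis angular-velocity recording for one shank: a
#' stationary lead-in (constant per-axis zero offsets plus sensor noise), a
#' 2-sample synchronization spike such as is produced by shaking the sensors,
#' a short settling gap, `n_strides` concatenated stride templates with
#' per-cycle log-normal jitter on durations and amplitudes, and a stationary
#' tail. The roll (`gx`) and yaw (`gy`) channels carry independently jittered,
#' scaled copies of the pitch waveform so that pitch dominates the axis
#' shares. The per-axis zero offsets persist through the whole recording,
#' emulating gyroscope bias.
#'
#' Ground truth for validation is attached as `attr(, "truth")`: the sync
#' time, absolute event times of every cycle, and the realized per-cycle
#' parameters.
#'
#' @param params A [cycle_params()] template for this leg.
#' @param n_strides Number of strides (>= 1).
#' @param config A [sim_config()].
#' @param phase_offset Extra delay (s) before this leg's first stride; use
#'   half a stride for the contralateral leg.
#' @param leg `"left"` or `"right"`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An [angvel_series()] with a `"truth"` attribute.
#' @export
simulate_leg <- function(params, n_strides, config, phase_offset = 0,
                         leg = c("left", "right"), seed = config$seed) {
  leg <- match.arg(leg)
  .vg_check(.is_scalar_num(n_strides) && n_strides >= 1,
            "simulate_leg: n_strides must be >= 1")
  .vg_check(.is_scalar_num(phase_offset) && phase_offset >= 0,
            "simulate_leg: phase_offset must be >= 0")
  validate_cycle_params(params)
  n_strides <- as.integer(n_strides)
  dt <- config$sample_interval

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  f_time <- .jitter_factors(n_strides, config$stride_time_cv)
  f_amp_z <- .jitter_factors(n_strides, config$amplitude_cv)
  f_amp_x <- .jitter_factors(n_strides, config$amplitude_cv)
  f_amp_y <- .jitter_factors(n_strides, config$amplitude_cv)

  z_cycles <- vector("list", n_strides)
  x_cycles <- vector("list", n_strides)
  y_cycles <- vector("list", n_strides)
  truth_cycles <- vector("list", n_strides)
  for (k in seq_len(n_strides)) {
    pz <- .scaled_params(params, f_time[k], f_amp_z[k])
    tz <- make_cycle_template(pz, dt)
    z_cycles[[k]] <- tz$values
    # roll/yaw: same cycle length, independently jittered amplitude copy
    frac <- config$roll_yaw_fraction
    if (frac > 0) {
      x_cycles[[k]] <- tz$values / f_amp_z[k] * f_amp_x[k] * frac
      y_cycles[[k]] <- tz$values / f_amp_z[k] * f_amp_y[k] * frac
    } else {
      x_cycles[[k]] <- numeric(tz$n)
      y_cycles[[k]] <- numeric(tz$n)
    }
    truth_cycles[[k]] <- list(n = tz$n, events = tz$events,
                              realized = tz$realized)
  }

  n_lead <- as.integer(round(config$stationary_lead / dt))
  n_gap <- as.integer(round(1.0 / dt))  # settling gap after the sync spike
  n_phase <- as.integer(round(phase_offset / dt))
  spike <- rep(config$sync_spike_amplitude, 2L)

  z <- c(numeric(n_lead), spike, numeric(n_gap + n_phase),
         unlist(z_cycles), numeric(n_lead))
  x <- c(numeric(n_lead), spike, numeric(n_gap + n_phase),
         unlist(x_cycles), numeric(n_lead))
  y <- c(numeric(n_lead), spike, numeric(n_gap + n_phase),
         unlist(y_cycles), numeric(n_lead))
  n <- length(z)
  if (config$noise_sd > 0) {
    x <- x + stats::rnorm(n, 0, config$noise_sd)
    y <- y + stats::rnorm(n, 0, config$noise_sd)
    z <- z + stats::rnorm(n, 0, config$noise_sd)
  }
  off <- config$stationary_offset
  x <- x + off[1]; y <- y + off[2]; z <- z + off[3]
  tt <- (seq_len(n) - 1L) * dt

  # absolute ground-truth event times
  walk_start <- (n_lead + 2L + n_gap + n_phase) * dt
  cycle_starts <- walk_start + c(0, cumsum(vapply(truth_cycles, `[[`, 1L, "n") * dt))
  cycle_starts <- cycle_starts[seq_len(n_strides)]
  truth <- list(
    sync_time = n_lead * dt,
    walk_start = walk_start,
    cycle_starts = cycle_starts,
    t_toeoff = cycle_starts + vapply(truth_cycles, function(c) c$events$t_toeoff, 0),
    t_midswing = cycle_starts + vapply(truth_cycles, function(c) c$events$t_midswing, 0),
    t_heelstrike = cycle_starts + vapply(truth_cycles, function(c) c$events$t_heelstrike, 0),
    realized = lapply(truth_cycles, `[[`, "realized"))

  out <- angvel_series(tt, x, y, z, leg = leg,
                       sensor_id = paste0("sim-", leg))
  attr(out, "truth") <- truth
  out
}

#' Simulate a bilateral corridor walk
#'
#' Generates both legs of one one-way corridor walk. The right leg is
#' phase-shifted by half a stride (the two legs move in reciprocally opposite
#' phases). The number of strides per leg is
#' `ceiling(corridor_length / (walking_speed * mean stride time))`. For the
#' `vn` group the lesion-side leg uses the matching vestibular-neuritis
#' template and the contralateral leg a 50/50 interpolation toward the
#' control template.
#'
#' @param config A [sim_config()].
#' @return A [walk_recording()] whose per-leg series carry `"truth"`
#'   attributes (see [simulate_leg()]).
#' @export
simulate_walk <- function(config) {
  .vg_check(inherits(config, "sim_config"),
            "simulate_walk: config must be a sim_config")
  mean_stride <- (config$left_params$stride_time +
                    config$right_params$stride_time) / 2
  n_strides <- as.integer(ceiling(
    config$corridor_length / (config$walking_speed * mean_stride)))
  left <- simulate_leg(config$left_params, n_strides, config,
                       phase_offset = 0, leg = "left",
                       seed = .sub_seed(config$seed, 1L))
  right <- simulate_leg(config$right_params, n_strides, config,
                        phase_offset = config$right_params$stride_time / 2,
                        leg = "right",
                        seed = .sub_seed(config$seed, 2L))
  walk_recording(left, right, group = config$group,
                 lesion_side = config$lesion_side,
                 corridor_length = config$corridor_length,
                 subject_meta = list(seed = config$seed,
                                     n_strides = n_strides))
}

#' Draw subject-level cycle parameters around a preset
#'
#' Samples one subject's template parameters from independent normal
#' distributions centred on a preset column with the published between-subject
#' SDs, for cohort-level simulation studies. Draws violating the template
#' invariants are redrawn.
#'
#' @param column `"normal"`, `"lvn"` or `"rvn"`.
#' @param seed Integer seed.
#' @return A [cycle_params()] object.
#' @export
draw_subject_params <- function(column = c("normal", "lvn", "rvn"), seed = 1L) {
  column <- match.arg(column)
  ref <- gait_reference_values()
  mcol <- paste0(column, "_mean"); scol <- paste0(column, "_sd")
  g <- function(param, col) ref[[col]][ref$parameter == param]
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  for (attempt in 1:100) {
    draw <- function(param) stats::rnorm(1, g(param, mcol), g(param, scol))
    swing <- draw("swing_time"); stance <- draw("stance_time")
    p <- try(cycle_params(
      stride_time = swing + stance, swing_time = swing, stance_time = stance,
      a_toeoff = draw("min_nav"), a_midswing = draw("max_nav"),
      up_slope = draw("up_slope"), down_slope = draw("down_slope")),
      silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
  .vg_stop("draw_subject_params: could not draw a valid parameter set")
}
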
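#' Build one sampled stride template of the pitch angular-velocity waveform
#'
#' Constructs the idealized single-stride waveform seen by a shank gyroscope's
#' pitch axis: a near-zero mid-stance plateau, a cosine-eased descent into the
#' toe-off trough, a linear rise at `up_slope` to the mid-swing peak, a descent
#' leaving the peak at `down_slope` that eases (cubic Hermite) into the
#' heel-strike trough, and a cosine-eased return to the plateau. All segment
#' junctions are continuous.
#'
#' Event times are snapped to the sampling grid so that the sampled extrema
#' equal the template amplitudes exactly; as a consequence segment durations
#' are quantized to one sample, and the realized slopes/durations can differ
#' from the requested values by a bounded half-sample effect (returned in
#' `$realized`). The heel-strike trough is placed at `toe-off + swing_time`,
#' so stride, swing and stance are realized to within half a sample; the
#' realized peak-to-heel-strike secant slope is then determined by the
#' amplitudes and the swing duration and is generally shallower than the
#' requested `down_slope` (which shapes the initial descent off the peak).
#'
#' @param params A [cycle_params()] object.
#' @param sample_interval Sampling interval in seconds (default 0.02).
#' @param strict If `TRUE` (default), `params` must pass
#'   [validate_cycle_params()]. With `strict = FALSE`, degenerate all-zero
#'   amplitude sets are admitted and yield a flat zero waveform.
#'
#' @return An object of class `cycle_template`: a list with `values` (deg/s,
#'   one stride of samples), `dt`, `n`, `events` (`t_toeoff`, `t_midswing`,
#'   `t_heelstrike`, `t_midstance` in stride-local seconds and the amplitudes
#'   at those times), `realized` (a `cycle_params` of realized durations and
#'   slopes) and `requested` (the input).
#' @export
make_cycle_template <- function(params, sample_interval = 0.02, strict = TRUE) {
  .vg_check(.is_scalar_num(sample_interval) && sample_interval > 0,
            "make_cycle_template: sample_interval must be > 0")
  dt <- sample_interval
  p <- params
  degenerate <- !strict && p$a_toeoff == 0 && p$a_midswing == 0 &&
    p$a_heelstrike == 0
  if (strict) validate_cycle_params(p)
  n_total <- max(2L, as.integer(round(p$stride_time / dt)))
  if (degenerate) {
    return(structure(
      list(values = numeric(n_total), dt = dt, n = n_total,
           events = NULL, realized = NULL, requested = p),
      class = "cycle_template"))
  }
  n_sw <- as.integer(round(p$swing_time / dt))
  .vg_check(n_sw >= 3L && n_sw < n_total,
            "make_cycle_template: swing_time must span >= 3 samples and be shorter than the stride")
  d_up <- (p$a_midswing - p$a_toeoff) / p$up_slope
  n_up <- max(1L, as.integer(round(d_up / dt)))
  .vg_check(n_up <= n_sw - 1L,
            "make_cycle_template: up-slope segment must fit inside the swing phase")
  n_ease <- 2L  # 40 ms plateau-transition easing at 50 Hz
  n_stance <- n_total - n_sw
  n_e <- max(n_ease, as.integer(floor(0.4 * n_stance)))
  .vg_check(n_e + n_sw + n_ease <= n_total,
            "make_cycle_template: stance plateau too short for the easing transitions")

  t <- (seq_len(n_total) - 1L) * dt
  v <- numeric(n_total)
  t_e <- n_e * dt
  t_f <- (n_e + n_up) * dt
  t_g <- (n_e + n_sw) * dt
  ease_w <- n_ease * dt

  # descent into toe-off trough (cosine, zero slope at the trough)
  idx <- which(t > t_e - ease_w & t <= t_e)
  v[idx] <- .ease_cos(t[idx] - (t_e - ease_w), 0, p$a_toeoff, ease_w)

  # linear rise to the mid-swing peak; slope realized on the snapped grid
  up_real <- (p$a_midswing - p$a_toeoff) / (n_up * dt)
  idx <- which(t > t_e & t <= t_f)
  v[idx] <- p$a_toeoff + up_real * (t[idx] - t_e)

  # descent: leave the peak at the requested down_slope, then cubic-Hermite
  # easing into the heel-strike trough at t_g (zero slope at the trough)
  W <- (n_sw - n_up) * dt
  D <- p$a_heelstrike - p$a_midswing   # < 0
  s <- p$down_slope                    # < 0
  descent <- function(tau) {           # tau in (0, W]
    if (abs(s) * W <= abs(D)) {
      # requested slope cannot reach the trough in time: straight secant
      p$a_midswing + (D / W) * tau
    } else {
      t_lin <- 2 * D / s - W           # duration of the linear part
      if (t_lin <= 0) {
        .hermite(tau, W, p$a_midswing, p$a_heelstrike, s, 0)
      } else {
        v_s <- p$a_midswing + s * t_lin
        ifelse(tau <= t_lin,
               p$a_midswing + s * tau,
               .hermite(tau - t_lin, W - t_lin, v_s, p$a_heelstrike, s, 0))
      }
    }
  }
  idx <- which(t > t_f & t <= t_g)
  v[idx] <- descent(t[idx] - t_f)

  # return to the mid-stance plateau
  idx <- which(t > t_g & t <= t_g + ease_w)
  v[idx] <- .ease_cos(t[idx] - t_g, p$a_heelstrike, 0, ease_w)

  realized <- cycle_params(
    stride_time = n_total * dt,
    swing_time = n_sw * dt,
    stance_time = (n_total - n_sw) * dt,
    a_toeoff = p$a_toeoff, a_midswing = p$a_midswing,
    a_heelstrike = p$a_heelstrike,
    up_slope = up_real,
    down_slope = D / W)

  structure(
    list(values = v, dt = dt, n = n_total,
         events = list(
           t_toeoff = t_e, t_midswing = t_f, t_heelstrike = t_g,
           t_midstance = t_g + ease_w,
           v_toeoff = p$a_toeoff, v_midswing = p$a_midswing,
           v_heelstrike = p$a_heelstrike, v_midstance = 0),
         realized = realized, requested = p),
    class = "cycle_template")
}

#' @export
print.cycle_template <- function(x, ...) {
  cat(sprintf("<cycle_template> %d samples @ %.0f Hz (%.2f s)\n",
              x$n, 1 / x$dt, x$n * x$dt))
  if (!is.null(x$events)) {
    cat(sprintf("  events (s): toe-off %.2f, mid-swing %.2f, heel-strike %.2f\n",
                x$events$t_toeoff, x$events$t_midswing, x$events$t_heelstrike))
  }
  invisible(x)
}
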
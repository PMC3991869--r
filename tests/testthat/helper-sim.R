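# shared fixtures built in code

# noise-free, zero-variability control simulation used by several files
quiet_cycles <- function(...) suppressMessages(detect_gait_cycles(...))

clean_leg_sim <- function(n_strides = 30, seed = 7,
                          params = default_params("control")) {
  cfg <- sim_config(noise_sd = 0, stride_time_cv = 0, amplitude_cv = 0,
                    seed = seed)
  simulate_leg(params, n_strides, cfg, leg = "left", seed = seed)
}

# run calibration + nav + event detection on one simulated leg
analyze_clean_leg <- function(series, max_sd = 10) {
  t0 <- detect_sync_start(series)
  off <- estimate_offsets(series, c(t0 - 4.5, t0 - 0.5), max_sd = max_sd)
  nav <- pitch_nav(series, off)
  cycles <- quiet_cycles(nav, segment = c(t0 + 0.5, max(series$time)))
  list(t0 = t0, offsets = off, nav = nav, cycles = cycles)
}

# a nav_series from a bare signal vector (via the public constructors)
signal_nav <- function(values, dt = 0.02) {
  tt <- (seq_along(values) - 1) * dt
  s <- angvel_series(tt, numeric(length(values)), numeric(length(values)),
                     values, leg = "left")
  pitch_nav(s, c(0, 0, 0), shares = FALSE)
}

# brute-force Mann-Whitney oracle: enumerate all assignments of the pooled
# sample to the two groups and compute the exact two-sided p for U
mwu_brute_force <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}
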
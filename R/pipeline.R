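#' Resolve a configuration list into a [sim_config()]
#'
#' Validates override keys against the generator's configuration surface and
#' errors on unknown keys (listing them) before any computation.
#'
#' @param overrides Named list of [sim_config()] arguments (possibly empty),
#'   or an existing `sim_config` (returned unchanged).
#' @return A `sim_config`.
#' @export
resolve_config <- function(overrides = list()) {
  if (inherits(overrides, "sim_config")) return(overrides)
  .vg_check(is.list(overrides), "resolve_config: overrides must be a list")
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(overrides), allowed)
  .vg_check(length(unknown) == 0L,
            sprintf("resolve_config: unknown config key(s): %s",
                    paste(unknown, collapse = ", ")))
  do.call(sim_config, overrides)
}

#' Analyze one leg's recording end to end
#'
#' Runs the single-leg chain: sync detection, stationary offset estimation
#' from the pre-sync window, pitch-signal extraction, cycle/event detection
#' (skipping the first half-second after the sync spike), and the walking
#' -segment power spectrum with dominant-frequency extraction. The walking
#' segment for the spectrum spans the detected mid-swing peaks padded by one
#' mean stride on each side, clipped to the recording.
#'
#' @param series An [angvel_series()].
#' @param jerk_threshold Sync threshold, deg/s per sample.
#' @param min_separation,prominence_frac Peak-detection settings
#'   (see [detect_midswing_peaks()]).
#' @return A list with `sync_time`, `offsets`, `nav`, `cycles` (the
#'   [detect_gait_cycles()] result), `spectrum`, `peaks`
#'   (dominant frequencies) and `axis_medians`.
#' @export
analyze_series <- function(series, jerk_threshold = 150,
                           min_separation = 0.5, prominence_frac = 0.4) {
  t0 <- detect_sync_start(series, jerk_threshold)
  t_start <- series$time[1]; t_end <- series$time[length(series$time)]
  w_start <- max(t_start, t0 - 4.6)
  w_end <- t0 - 0.1
  .vg_check(w_end - w_start >= 1,
            "analyze_series: less than 1 s of pre-sync stationary data for offset estimation")
  offsets <- estimate_offsets(series, c(w_start, w_end))
  nav <- pitch_nav(series, offsets)
  cycles <- detect_gait_cycles(nav, min_separation, prominence_frac,
                               segment = c(t0 + 0.5, t_end))
  peaks_t <- cycles$peak_times
  mean_stride <- mean(diff(peaks_t))
  seg <- c(max(t_start, peaks_t[1] - mean_stride),
           min(t_end, peaks_t[length(peaks_t)] + mean_stride))
  spectrum <- power_spectrum(nav, seg)
  peaks <- dominant_frequencies(spectrum)
  axis_medians <- median_axis_share(nav$shares, seg)
  list(sync_time = t0, offsets = offsets, nav = nav, cycles = cycles,
       walking_segment = seg, spectrum = spectrum, peaks = peaks,
       axis_medians = axis_medians)
}

#' Analyze a bilateral walk recording
#'
#' Applies [analyze_series()] to each leg and aggregates with
#' [summarize_walk()].
#'
#' @param recording A [walk_recording()].
#' @param ... Passed to [analyze_series()].
#' @return A list with per-leg `left`/`right` analyses and `summary`
#'   (the [summarize_walk()] pair).
#' @export
analyze_recording <- function(recording, ...) {
  left <- analyze_series(recording$left, ...)
  right <- analyze_series(recording$right, ...)
  summary <- summarize_walk(recording, left$cycles, right$cycles)
  list(left = left, right = right, summary = summary)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows", pretty = TRUE)
  path
}

.summary_payload <- function(summary) {
  lapply(summary, function(s) {
    list(leg = s$leg,
         mean = as.list(s$mean), sd = as.list(s$sd),
         n_strides = s$n_strides, gait_velocity = s$gait_velocity,
         walk_duration = s$walk_duration,
         var_toeoff_time = s$var_toeoff_time,
         var_heelstrike_time = s$var_heelstrike_time)
  })
}

#' Simulate a walk and write it as a sensor-file recording
#'
#' @param config A `sim_config` or named override list (see
#'   [resolve_config()]).
#' @param out_dir Output directory; receives `left.csv`, `right.csv`, YAML
#'   sidecars and a `config.yaml` echo of the resolved configuration.
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config = list(), out_dir) {
  config <- resolve_config(config)
  rec <- simulate_walk(config)
  write_recording(rec, out_dir)
  echo <- config
  echo$left_params <- unclass(echo$left_params)
  echo$right_params <- unclass(echo$right_params)
  yaml::write_yaml(unclass(echo), file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Full analysis pipeline over a recording directory
#'
#' Orchestrates simulate (optional) / read, sensor alignment, offset
#' calibration, pitch-signal extraction, event detection, spectral analysis
#' and summary export. Writes `cycles.csv` (one row per cycle with a `leg`
#' column), `summary.json`, `peaks.json` and a machine-readable
#' `manifest.json` (resolved seed, stage timings, skipped-cycle counts) into
#' `out_dir`. Identical inputs and configuration produce byte-identical
#' numeric outputs.
#'
#' @param out_dir Output directory.
#' @param input_dir Directory with an existing recording
#'   (see [read_recording()]); if `NULL`, a walk is simulated from `config`
#'   into `file.path(out_dir, "recording")`.
#' @param config `sim_config` or override list used when simulating.
#' @param ... Passed to [analyze_series()].
#' @return Invisibly, a list with the analysis, summary and artifact paths.
#' @export
run_full <- function(out_dir, input_dir = NULL, config = list(), ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      .vg_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    message(sprintf("[vestigait] stage %-10s %6.2f s", name, timings[[name]]))
    res
  }
  if (is.null(input_dir)) {
    config <- resolve_config(config)
    input_dir <- file.path(out_dir, "recording")
    stage("simulate", run_simulate(config, input_dir))
  }
  rec <- stage("read", read_recording(input_dir))
  rec <- stage("align", align_pair(
    rec$left, rec$right, group = rec$group, lesion_side = rec$lesion_side,
    corridor_length = rec$corridor_length, subject_meta = rec$subject_meta))
  analysis <- stage("analyze", analyze_recording(rec, ...))

  cyc <- rbind(cbind(analysis$left$cycles$cycles, leg = "left"),
               cbind(analysis$right$cycles$cycles, leg = "right"))
  cycles_path <- file.path(out_dir, "cycles.csv")
  utils::write.csv(cyc, cycles_path, row.names = FALSE)
  summary_path <- file.path(out_dir, "summary.json")
  .write_json(.summary_payload(analysis$summary), summary_path)
  peaks_path <- file.path(out_dir, "peaks.json")
  .write_json(list(left = list(f = analysis$left$peaks$f,
                               amp = analysis$left$peaks$amp),
                   right = list(f = analysis$right$peaks$f,
                                amp = analysis$right$peaks$amp)),
              peaks_path)
  manifest <- list(
    input_dir = input_dir,
    group = rec$group, lesion_side = rec$lesion_side,
    corridor_length = rec$corridor_length,
    seed = if (inherits(config, "sim_config")) config$seed else NULL,
    skipped_cycles = list(left = analysis$left$cycles$n_skipped,
                          right = analysis$right$cycles$n_skipped),
    stage_timings_s = timings)
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(analysis = analysis, summary = analysis$summary,
                 paths = list(cycles = cycles_path, summary = summary_path,
                              peaks = peaks_path)))
}

#' Spectral stage over a recording directory
#'
#' @param input_dir Recording directory (see [read_recording()]).
#' @param out_json Output path for the dominant-frequency JSON.
#' @param out_csv Optional path for the full `frequency,power` spectrum CSV
#'   (both legs).
#' @param ... Passed to [analyze_series()].
#' @return Invisibly, the per-leg `spectral_peaks`.
#' @export
run_spectrum <- function(input_dir, out_json, out_csv = NULL, ...) {
  rec <- read_recording(input_dir)
  rec <- align_pair(rec$left, rec$right, group = rec$group,
                    lesion_side = rec$lesion_side,
                    corridor_length = rec$corridor_length)
  left <- analyze_series(rec$left, ...)
  right <- analyze_series(rec$right, ...)
  .write_json(list(left = list(f = left$peaks$f, amp = left$peaks$amp),
                   right = list(f = right$peaks$f, amp = right$peaks$amp)),
              out_json)
  if (!is.null(out_csv)) {
    utils::write.csv(
      rbind(data.frame(leg = "left", frequency = left$spectrum$freq,
                       power = left$spectrum$power),
            data.frame(leg = "right", frequency = right$spectrum$freq,
                       power = right$spectrum$power)),
      out_csv, row.names = FALSE)
  }
  invisible(list(left = left$peaks, right = right$peaks))
}

#' Simulate and analyze a cohort of subjects
#'
#' Round-trip cohort generator for validation and power studies: each
#' subject's template parameters are drawn around a preset column with the
#' published between-subject SDs, a walk is simulated and fully analyzed,
#' and one summary row per subject is returned (the lesion-side leg for
#' patients, the left leg for controls, matching the left-leg analysis
#' perspective).
#'
#' @param n_control,n_lvn,n_rvn Subjects per group.
#' @param seed Integer master seed.
#' @param corridor_length Corridor length in metres (default 88.8).
#' @param stride_time_cv,amplitude_cv,noise_sd Within-walk variability
#'   settings passed to [sim_config()].
#' @return A data frame with one row per subject: the parameter means,
#'   `gait_velocity`, `n_strides`, event-timing variances, `leg` and
#'   `group`.
#' @export
simulate_cohort <- function(n_control = 10, n_lvn = 5, n_rvn = 5, seed = 1L,
                            corridor_length = 88.8, stride_time_cv = 0.03,
                            amplitude_cv = 0.05, noise_sd = 5) {
  spec <- rbind(
    if (n_control > 0) data.frame(group = "normal", n = n_control),
    if (n_lvn > 0) data.frame(group = "lvn", n = n_lvn),
    if (n_rvn > 0) data.frame(group = "rvn", n = n_rvn))
  rows <- list()
  subj <- 0L
  for (i in seq_len(nrow(spec))) {
    g <- spec$group[i]
    for (j in seq_len(spec$n[i])) {
      subj <- subj + 1L
      s <- .sub_seed(seed, subj)
      params <- draw_subject_params(
        switch(g, normal = "normal", lvn = "lvn", rvn = "rvn"), seed = s)
      cfg <- switch(g,
        normal = sim_config(group = "control", left_params = params,
                            right_params = params,
                            corridor_length = corridor_length,
                            stride_time_cv = stride_time_cv,
                            amplitude_cv = amplitude_cv, noise_sd = noise_sd,
                            seed = s),
        lvn = sim_config(group = "vn", lesion_side = "left",
                         left_params = params,
                         corridor_length = corridor_length,
                         stride_time_cv = stride_time_cv,
                         amplitude_cv = amplitude_cv, noise_sd = noise_sd,
                         seed = s),
        rvn = sim_config(group = "vn", lesion_side = "right",
                         right_params = params,
                         corridor_length = corridor_length,
                         stride_time_cv = stride_time_cv,
                         amplitude_cv = amplitude_cv, noise_sd = noise_sd,
                         seed = s))
      rec <- simulate_walk(cfg)
      rec <- align_pair(rec$left, rec$right, group = rec$group,
                        lesion_side = rec$lesion_side,
                        corridor_length = rec$corridor_length)
      analysis <- suppressMessages(analyze_recording(rec))
      leg <- if (g == "rvn") "right" else "left"
      row <- summary_row(analysis$summary[[leg]])
      row$group <- g
      row$subject <- subj
      rows[[subj]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Group comparison over a cohort table
#'
#' Runs [build_report()] on a per-subject table (e.g. from
#' [simulate_cohort()]) and writes CSV/JSON artifacts.
#'
#' @param data Per-subject data frame with a `group` column.
#' @param out_csv,out_json Optional output paths.
#' @param ... Passed to [build_report()].
#' @return The `gait_report`, invisibly.
#' @export
run_compare <- function(data, out_csv = NULL, out_json = NULL, ...) {
  report <- build_report(data, ...)
  write_report(report, csv = out_csv, json = out_json)
  invisible(report)
}
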
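#' Construct an angular-velocity series
#'
#' Container for one sensor's 3-axis angular-velocity stream. Axis
#' conventions follow the sensor mounting on the shank: `gx` is the
#' antigravity axis (roll), `gy` the walking-direction axis (yaw), and `gz`
#' the right-pointing axis whose rotation is the shank pitch. Timestamps must
#' be uniformly spaced (tolerance 1e-6 s).
#'
#' @param timestamps Numeric vector of seconds, strictly increasing, uniform.
#' @param gx,gy,gz Numeric vectors of deg/s, same length as `timestamps`.
#' @param leg `"left"` or `"right"`.
#' @param sensor_id Free-text sensor identifier.
#' @return An object of class `angvel_series`.
#' @export
angvel_series <- function(timestamps, gx, gy, gz,
                          leg = c("left", "right"), sensor_id = "sensor") {
  leg <- match.arg(leg)
  n <- length(timestamps)
  .vg_check(n >= 2L, "angvel_series: need at least 2 samples")
  .vg_check(length(gx) == n && length(gy) == n && length(gz) == n,
            "angvel_series: all three channels must match the timestamp length")
  .vg_check(all(is.finite(timestamps)) && all(is.finite(gx)) &&
              all(is.finite(gy)) && all(is.finite(gz)),
            "angvel_series: non-finite values")
  d <- diff(timestamps)
  .vg_check(all(d > 0), "angvel_series: timestamps must be strictly increasing")
  dt <- stats::median(d)
  .vg_check(max(abs(d - dt)) <= 1e-6,
            "angvel_series: timestamps must be uniformly spaced (tolerance 1e-6 s)")
  structure(
    list(time = as.numeric(timestamps), gx = as.numeric(gx),
         gy = as.numeric(gy), gz = as.numeric(gz),
         dt = dt, leg = leg, sensor_id = sensor_id),
    class = "angvel_series")
}

#' @export
print.angvel_series <- function(x, ...) {
  cat(sprintf("<angvel_series> %s leg, %d samples @ %.0f Hz, t in [%.2f, %.2f] s\n",
              x$leg, length(x$time), 1 / x$dt, x$time[1],
              x$time[length(x$time)]))
  invisible(x)
}

#' @export
as.data.frame.angvel_series <- function(x, ...) {
  data.frame(t = x$time, gx = x$gx, gy = x$gy, gz = x$gz)
}

#' Read an angular-velocity series from CSV
#'
#' Parses a comma-separated file with a header naming the columns `t`, `gx`,
#' `gy`, `gz` (in any order; parsing is header-driven). Timestamps are in
#' seconds, channels in deg/s. Sub-microsecond timestamp jitter is accepted
#' and re-gridded to an exactly uniform grid; larger irregularities are
#' rejected with the offending row number. A uniform rate other than 50 Hz is
#' accepted with a warning and linearly resampled to 50 Hz.
#'
#' @param path Path to the CSV file.
#' @param leg `"left"` or `"right"`.
#' @param sensor_id Sensor identifier to attach.
#' @return An [angvel_series()].
#' @export
read_series <- function(path, leg = c("left", "right"), sensor_id = "sensor") {
  leg <- match.arg(leg)
  .vg_check(file.exists(path), sprintf("read_series: file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "gx", "gy", "gz")
  missing_cols <- setdiff(need, names(df))
  .vg_check(length(missing_cols) == 0L,
            sprintf("read_series: missing column(s): %s",
                    paste(missing_cols, collapse = ", ")))
  .vg_check(nrow(df) >= 2L, "read_series: need at least 2 data rows")
  for (col in need) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(vals))
    .vg_check(length(bad) == 0L,
              sprintf("read_series: non-numeric value in column '%s' at data row %d",
                      col, if (length(bad)) bad[1] else 0L))
    df[[col]] <- vals
  }
  tt <- df$t
  d <- diff(tt)
  bad <- which(d <= 0)
  .vg_check(length(bad) == 0L,
            sprintf("read_series: timestamps not increasing at data row %d", bad[1] + 1L))
  dt <- stats::median(d)
  dev <- abs(d - dt)
  bad <- which(dev > 1e-6)
  .vg_check(length(bad) == 0L,
            sprintf("read_series: irregular sampling at data row %d (gap %.6g s, expected %.6g s)",
                    bad[1] + 1L, d[bad[1]], dt))
  # re-grid sub-microsecond jitter to an exact uniform grid
  tt <- tt[1] + (seq_along(tt) - 1L) * dt
  target <- 0.02
  if (abs(dt - target) > 1e-9) {
    warning(sprintf(
      "read_series: sampling interval %.6g s differs from 0.02 s; resampling to 50 Hz",
      dt))
    new_t <- seq(tt[1], tt[length(tt)], by = target)
    df <- data.frame(
      t = new_t,
      gx = stats::approx(tt, df$gx, xout = new_t)$y,
      gy = stats::approx(tt, df$gy, xout = new_t)$y,
      gz = stats::approx(tt, df$gz, xout = new_t)$y)
    tt <- new_t
  }
  angvel_series(tt, df$gx, df$gy, df$gz, leg = leg, sensor_id = sensor_id)
}

#' Write an angular-velocity series to CSV
#'
#' Writes the `t,gx,gy,gz` CSV dialect read by [read_series()], with enough
#' decimal digits for full round-trip precision.
#'
#' @param series An `angvel_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  df <- as.data.frame(series)
  out <- vapply(df, function(col) sprintf("%.12g", col), character(nrow(df)))
  lines <- c("t,gx,gy,gz", apply(out, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a bilateral walk recording
#'
#' Pairs the two per-leg series with the walk-level metadata (group, lesion
#' side, corridor length, free-form subject data).
#'
#' @param left,right `angvel_series` objects with matching `leg` fields.
#' @param group `"control"` or `"vn"`.
#' @param lesion_side `"left"`, `"right"` or `"none"`.
#' @param corridor_length Corridor length in metres (> 0).
#' @param subject_meta Named list of free-form subject metadata.
#' @return An object of class `walk_recording`.
#' @export
walk_recording <- function(left, right, group = c("control", "vn"),
                           lesion_side = c("none", "left", "right"),
                           corridor_length = 88.8, subject_meta = list()) {
  group <- match.arg(group)
  lesion_side <- match.arg(lesion_side)
  .vg_check(inherits(left, "angvel_series") && left$leg == "left",
            "walk_recording: 'left' must be an angvel_series with leg = 'left'")
  .vg_check(inherits(right, "angvel_series") && right$leg == "right",
            "walk_recording: 'right' must be an angvel_series with leg = 'right'")
  .vg_check(.is_scalar_num(corridor_length) && corridor_length > 0,
            "walk_recording: corridor_length must be > 0")
  structure(
    list(left = left, right = right, group = group,
         lesion_side = lesion_side, corridor_length = corridor_length,
         subject_meta = subject_meta),
    class = "walk_recording")
}

#' @export
print.walk_recording <- function(x, ...) {
  cat(sprintf("<walk_recording> group=%s lesion=%s corridor=%.1f m\n",
              x$group, x$lesion_side, x$corridor_length))
  print(x$left); print(x$right)
  invisible(x)
}

#' Write a walk recording to a directory
#'
#' Emits `left.csv` and `right.csv` (via [write_series()]) plus per-leg YAML
#' sidecars carrying the leg, sensor id, group, lesion side, corridor length
#' and subject metadata.
#'
#' @param recording A `walk_recording`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (leg in c("left", "right")) {
    s <- recording[[leg]]
    write_series(s, file.path(dir, paste0(leg, ".csv")))
    meta <- list(leg = leg, sensor_id = s$sensor_id,
                 group = recording$group,
                 lesion_side = recording$lesion_side,
                 corridor_length_m = recording$corridor_length,
                 subject_meta = recording$subject_meta)
    yaml::write_yaml(meta, file.path(dir, paste0(leg, ".yaml")))
  }
  invisible(dir)
}

#' Read a walk recording from a directory written by [write_recording()]
#'
#' @param dir Directory containing `left.csv`, `right.csv` and their YAML
#'   sidecars.
#' @return A `walk_recording`.
#' @export
read_recording <- function(dir) {
  series <- list()
  meta <- NULL
  for (leg in c("left", "right")) {
    ypath <- file.path(dir, paste0(leg, ".yaml"))
    m <- if (file.exists(ypath)) yaml::read_yaml(ypath) else list()
    if (is.null(meta)) meta <- m
    series[[leg]] <- read_series(file.path(dir, paste0(leg, ".csv")),
                                 leg = leg,
                                 sensor_id = m$sensor_id %||% "sensor")
  }
  walk_recording(series$left, series$right,
                 group = meta$group %||% "control",
                 lesion_side = meta$lesion_side %||% "none",
                 corridor_length = meta$corridor_length_m %||% 88.8,
                 subject_meta = meta$subject_meta %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
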
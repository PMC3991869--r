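#' Power spectrum of the pitch signal over a walking segment
#'
#' Mean-removed, Hann-windowed magnitude-squared spectrum of the pitch
#' angular velocity. A single full-segment periodogram is used rather than
#' averaged short windows: corridor walks last on the order of a minute and
#' the quantity of interest is peak location, not the variance of the
#' spectral estimate. The segment must span at least 10 s so the frequency
#' resolution is 0.1 Hz or better.
#'
#' @param nav A [pitch_nav()] series.
#' @param segment Optional `(t0, t1)` selecting the walking segment; default
#'   is the whole series.
#' @return A list of class `nav_spectrum`: `freq` (Hz, one-sided),
#'   `power` (normalized so the 0.3-6 Hz band sums to 1), `psd_raw`
#'   (one-sided, sums to the windowed time-domain energy), `df` (bin width)
#'   and `duration`.
#' @export
power_spectrum <- function(nav, segment = NULL) {
  .vg_check(inherits(nav, "nav_series"),
            "power_spectrum: nav must be a nav_series")
  sel <- rep(TRUE, length(nav$time))
  if (!is.null(segment)) sel <- nav$time >= segment[1] & nav$time <= segment[2]
  x <- nav$nav[sel]
  n <- length(x)
  duration <- n * nav$dt
  .vg_check(duration >= 10,
            sprintf("power_spectrum: segment too short (%.1f s; need >= 10 s for 0.1 Hz resolution)",
                    duration))
  x <- x - mean(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))  # Hann
  xw <- x * w
  X <- stats::fft(xw)
  half <- seq_len(floor(n / 2) + 1L)
  p2 <- Mod(X)^2 / n                     # two-sided, sums to energy of xw
  psd <- p2[half]
  dbl <- half > 1L & half < (n - half + 2L)  # interior bins appear twice
  psd[dbl] <- 2 * psd[dbl]
  freq <- (half - 1L) / duration
  band <- freq >= 0.3 & freq <= 6
  .vg_check(any(band), "power_spectrum: no bins in the 0.3-6 Hz band")
  total <- sum(psd[band])
  structure(
    list(freq = freq, power = if (total > 0) psd / total else psd,
         psd_raw = psd, df = 1 / duration, duration = duration),
    class = "nav_spectrum")
}

#' Extract the dominant gait frequencies
#'
#' Finds local maxima of the power spectrum inside the 0.3-6 Hz gait band
#' (below 0.3 Hz is drift, above 6 Hz noise for normal walking), keeps those
#' with prominence at least `prominence_frac` of the band maximum, selects
#' the `n_peaks` largest by power, and returns them ordered by ascending
#' frequency as `f1 < f2 < f3`. For steady gait, `f1` is the stride
#' (cadence) frequency and `f2`, `f3` its harmonics. If fewer than `n_peaks`
#' qualify, the missing entries are `NA`.
#'
#' @param spectrum A [power_spectrum()] result.
#' @param n_peaks Number of dominant peaks to report (default 3).
#' @param prominence_frac Prominence threshold as a fraction of the band
#'   maximum (default 0.05).
#' @return A list of class `spectral_peaks` with `f` (Hz) and `amp`
#'   (normalized power), each of length `n_peaks`.
#' @export
dominant_frequencies <- function(spectrum, n_peaks = 3L,
                                 prominence_frac = 0.05) {
  .vg_check(inherits(spectrum, "nav_spectrum"),
            "dominant_frequencies: spectrum must come from power_spectrum()")
  band <- spectrum$freq >= 0.3 & spectrum$freq <= 6
  f <- spectrum$freq[band]; p <- spectrum$power[band]
  cand <- .local_maxima(p)
  if (length(cand)) {
    prom <- vapply(cand, function(i) .prominence(p, i), 0)
    cand <- cand[prom >= prominence_frac * max(p)]
  }
  ord <- cand[order(p[cand], decreasing = TRUE)]
  sel <- sort(utils::head(ord, n_peaks))
  fs <- rep(NA_real_, n_peaks); amps <- rep(NA_real_, n_peaks)
  if (length(sel)) {
    fs[seq_along(sel)] <- f[sel]
    amps[seq_along(sel)] <- p[sel]
  }
  if (length(sel) < n_peaks) {
    message(sprintf("dominant_frequencies: only %d of %d qualifying peaks found",
                    length(sel), n_peaks))
  }
  structure(list(f = fs, amp = amps), class = "spectral_peaks")
}

#' @export
print.spectral_peaks <- function(x, ...) {
  cat("<spectral_peaks>",
      paste(sprintf("f%d = %.3f Hz", seq_along(x$f), x$f), collapse = ", "),
      "\n")
  invisible(x)
}
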
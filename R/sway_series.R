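#' Uniformly sampled quiet-standing force-plate signals
#'
#' A `sway_series` bundles the anterior-posterior (AP) centre-of-pressure
#' displacement and AP ground-reaction force of one trial segment on a uniform
#' time grid. Sample `k` (1-based) is taken at time `t0 + (k - 1) / fs`.
#' Units are fixed throughout the package: seconds for time, millimetres for
#' COP displacement and newtons for force.
#'
#' @param fs Sampling rate in Hz (> 0).
#' @param cop_x AP COP displacement samples (mm).
#' @param grf_x AP ground-reaction-force samples (N), same length as `cop_x`.
#' @param grf_z Optional vertical force samples (N), same length.
#' @param t0 Time of the first sample (s).
#'
#' @return An object of class `sway_series`: a list with fields `fs`, `t0`,
#'   `cop_x`, `grf_x` and (possibly `NULL`) `grf_z`.
#' @examples
#' s <- sway_series(fs = 100, cop_x = sin(seq(0, 2 * pi, length.out = 201)),
#'                  grf_x = cos(seq(0, 2 * pi, length.out = 201)))
#' sway_duration(s)
#' @export
sway_series <- function(fs, cop_x, grf_x, grf_z = NULL, t0 = 0) {
  s <- structure(
    list(fs = as.numeric(fs), t0 = as.numeric(t0),
         cop_x = as.numeric(cop_x), grf_x = as.numeric(grf_x),
         grf_z = if (!is.null(grf_z)) as.numeric(grf_z)),
    class = "sway_series")
  validate_sway_series(s)
}

validate_sway_series <- function(s) {
  stopifnot(inherits(s, "sway_series"))
  if (!is.finite(s$fs) || s$fs <= 0) stop("`fs` must be a positive finite number")
  if (!is.finite(s$t0)) stop("`t0` must be finite")
  n <- length(s$cop_x)
  if (n < 2) stop("a sway_series needs at least 2 samples")
  if (length(s$grf_x) != n) stop("`cop_x` and `grf_x` must have the same length")
  if (!is.null(s$grf_z) && length(s$grf_z) != n)
    stop("`grf_z` must match the length of the other channels")
  if (!all(is.finite(s$cop_x)) || !all(is.finite(s$grf_x)) ||
      (!is.null(s$grf_z) && !all(is.finite(s$grf_z))))
    stop("all channel values must be finite")
  s
}

#' Sample times of a sway series
#' @param s A [sway_series()].
#' @return Numeric vector of sample times (s).
#' @export
sway_times <- function(s) s$t0 + (seq_along(s$cop_x) - 1L) / s$fs

#' Number of samples in a sway series
#' @param s A [sway_series()].
#' @return Integer sample count.
#' @export
sway_length <- function(s) length(s$cop_x)

#' Duration of a sway series
#' @param s A [sway_series()].
#' @return Recorded span `(n - 1) / fs` in seconds.
#' @export
sway_duration <- function(s) (sway_length(s) - 1L) / s$fs

#' @export
print.sway_series <- function(x, ...) {
  cat(sprintf("<sway_series> %d samples @ %g Hz, t = [%g, %g] s%s\n",
              sway_length(x), x$fs, x$t0, x$t0 + sway_duration(x),
              if (is.null(x$grf_z)) "" else ", with grf_z"))
  cat(sprintf("  cop_x: [%.3f, %.3f] mm   grf_x: [%.3f, %.3f] N\n",
              min(x$cop_x), max(x$cop_x), min(x$grf_x), max(x$grf_x)))
  invisible(x)
}

#' Extract a time window from a sway series
#'
#' Returns the samples whose time stamps fall in `[start_s, end_s]`, with `t0`
#' updated to the first retained sample. Typical use is cutting the analysed
#' 30 s segment (e.g. 5 s to 35 s) out of a longer recording.
#'
#' @param s A [sway_series()].
#' @param start_s,end_s Window bounds in seconds; must lie inside the recorded
#'   span with `end_s > start_s`.
#' @return A [sway_series()] restricted to the window.
#' @export
extract_window <- function(s, start_s, end_s) {
  validate_sway_series(s)
  if (end_s <= start_s) stop("`end_s` must be greater than `start_s`")
  t <- sway_times(s)
  eps <- 1e-9 / s$fs
  if (start_s < t[1] - eps || end_s > t[length(t)] + eps)
    stop("window lies outside the recorded span")
  keep <- which(t >= start_s - eps & t <= end_s + eps)
  if (length(keep) < 2) stop("window contains fewer than 2 samples")
  sway_series(fs = s$fs, t0 = t[keep[1]],
              cop_x = s$cop_x[keep], grf_x = s$grf_x[keep],
              grf_z = if (!is.null(s$grf_z)) s$grf_z[keep])
}

#' Resample a sway series onto a uniform grid
#'
#' Channels are linearly interpolated onto a uniform grid at `target_fs`.
#' Linear interpolation is appropriate here because trial signals are low-pass
#' filtered (band-limited well below any practical target rate) before any
#' rate change. With `include_endpoints = TRUE` the grid contains both the
#' first and last time instants of the input span, so a 30 s span resampled
#' at 30 Hz yields 901 points; the realised rate is then `(n - 1) / span`.
#'
#' @param s A [sway_series()].
#' @param target_fs Target sampling rate (Hz).
#' @param include_endpoints Logical; pin the grid to both span endpoints.
#' @return A resampled [sway_series()].
#' @export
resample_uniform <- function(s, target_fs, include_endpoints = TRUE) {
  validate_sway_series(s)
  if (!is.finite(target_fs) || target_fs <= 0) stop("`target_fs` must be positive")
  t <- sway_times(s)
  span <- t[length(t)] - t[1]
  if (span <= 0) stop("series duration must be positive")
  if (include_endpoints) {
    n_new <- floor(span * target_fs + 1e-9) + 1L
    if (n_new < 2) stop("target grid would have fewer than 2 points")
    grid <- seq(t[1], t[length(t)], length.out = n_new)
    fs_new <- (n_new - 1L) / span
  } else {
    n_new <- floor(span * target_fs + 1e-9) + 1L
    if (n_new < 2) stop("target grid would have fewer than 2 points")
    grid <- t[1] + (seq_len(n_new) - 1L) / target_fs
    fs_new <- target_fs
  }
  interp <- function(y) stats::approx(t, y, xout = grid, rule = 2)$y
  sway_series(fs = fs_new, t0 = grid[1],
              cop_x = interp(s$cop_x), grf_x = interp(s$grf_x),
              grf_z = if (!is.null(s$grf_z)) interp(s$grf_z))
}
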
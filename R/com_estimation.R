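#' Reconstruct the AP COM trajectory by zero-point-to-zero-point double integration
#'
#' Newton's second law ties the AP COM acceleration to the measured force for
#' any body, single- or multi-segment: `m * x..(t) = GRF_x(t)`. Double
#' integration therefore recovers the COM shape up to an unknown line
#' `C1 (t - t_i) + C0`. The zero-point method fixes that line with the
#' inverted-pendulum boundary condition: whenever `GRF_x = 0` the COM is
#' vertically over the COP, so between each pair of consecutive GRF zero
#' instants `t_i < t_{i+1}`
#'
#'   `x(t) = (1/m) * double-integral of GRF_x from t_i + C1 (t - t_i) + C0`
#'
#' with `C0`, `C1` solved so that `x(t_i) = p_x(t_i)` and
#' `x(t_{i+1}) = p_x(t_{i+1})`. Of the anthropometric constants only the mass
#' enters; the validity index downstream is additionally invariant to any
#' rescaling of the reconstructed COP error. `estimate_com` applies the
#' segment integral over all consecutive crossing pairs. Samples before
#' the first crossing and after the last (where only one boundary condition is
#' available) are marked invalid rather than extrapolated, as are segments
#' shorter than 3 samples.
#'
#' The double integral is evaluated with the cumulative trapezoidal rule on
#' the native sample grid, starting from the (generally off-grid) interpolated
#' crossing instant with a partial first step; COP values at the crossing
#' instants are linearly interpolated.
#'
#' @param s A [sway_series()], low-pass filtered (see [butterworth_lowpass()]).
#' @param anthro An [anthro_model()].
#' @param min_gap_s Minimum crossing spacing passed to
#'   [find_grf_zero_crossings()].
#' @return An object of class `com_trajectory`: a list with per-sample fields
#'   `x` (reconstructed AP COM, mm; `NA` outside valid segments), `e_x`
#'   (COP error `x - cop_x`, mm), `valid` (logical mask), plus `crossings`
#'   (the [find_grf_zero_crossings()] result), `series` and `anthro`.
#'   With fewer than 2 crossings an all-invalid trajectory is returned with a
#'   warning.
#' @examples
#' sim <- simulate_ip(ip_sim_config(seed = 1, duration_s = 10))
#' com <- estimate_com(butterworth_lowpass(sim$series), sim$config$anthro)
#' summary(com)
#' @seealso [trial_features()], [ipvi()]
#' @export
estimate_com <- function(s, anthro, min_gap_s = 0.02) {
  validate_sway_series(s)
  stopifnot(inherits(anthro, "anthro_model"))
  zc <- find_grf_zero_crossings(s, min_gap_s = min_gap_s)
  n <- sway_length(s)
  x <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  if (nrow(zc) < 2) {
    warning("fewer than 2 GRF zero crossings: COM trajectory is all-invalid")
  } else {
    for (j in seq_len(nrow(zc) - 1L)) {
      seg <- integrate_segment_impl(s, anthro$m, zc$time[j], zc$time[j + 1L])
      if (!is.null(seg)) {
        x[seg$idx] <- seg$x
        valid[seg$idx] <- TRUE
      }
    }
  }
  e_x <- ifelse(valid, x - s$cop_x, NA_real_)
  structure(list(x = x, e_x = e_x, valid = valid, crossings = zc,
                 series = s, anthro = anthro),
            class = "com_trajectory")
}

#' Double-integrate the GRF over one zero-to-zero segment
#'
#' Workhorse of [estimate_com()]; exposed for testing and for studying single
#' segments. `t_i` and `t_ip1` must be zero instants of `grf_x` (normally two
#' consecutive rows of [find_grf_zero_crossings()]).
#'
#' @param s A [sway_series()].
#' @param anthro An [anthro_model()].
#' @param t_i,t_ip1 Segment boundaries (s), `t_i < t_ip1`.
#' @return A list with `idx` (sample indices inside `[t_i, t_ip1]`) and `x`
#'   (reconstructed COM at those samples, mm), or `NULL` when the segment
#'   spans fewer than 3 samples (underdetermined numerics).
#' @export
integrate_segment <- function(s, anthro, t_i, t_ip1) {
  validate_sway_series(s)
  stopifnot(inherits(anthro, "anthro_model"))
  if (t_ip1 <= t_i) stop("`t_ip1` must be greater than `t_i`")
  integrate_segment_impl(s, anthro$m, t_i, t_ip1)
}

# Linear interpolation of channel y on the uniform grid t0 + (k-1)/fs.
interp_uniform <- function(y, t0, fs, tq) {
  u <- (tq - t0) * fs
  j <- pmin(pmax(floor(u), 0), length(y) - 2)
  frac <- u - j
  y[j + 1] * (1 - frac) + y[j + 2] * frac
}

integrate_segment_impl <- function(s, mass, t_i, t_ip1) {
  fs <- s$fs
  eps <- 1e-9 / fs
  i_first <- ceiling((t_i - s$t0 - eps) * fs) + 1L
  i_last <- floor((t_ip1 - s$t0 + eps) * fs) + 1L
  i_first <- max(i_first, 1L); i_last <- min(i_last, sway_length(s))
  if (i_last - i_first + 1L < 3L) return(NULL)
  idx <- i_first:i_last

  # augmented grid: interpolated crossing instants plus native samples between
  ta <- s$t0 + (idx - 1L) / fs
  ga <- s$grf_x[idx]
  lead <- ta[1] - t_i > eps          # t_i strictly before the first kept sample
  trail <- t_ip1 - ta[length(ta)] > eps
  if (lead) { ta <- c(t_i, ta); ga <- c(0, ga) } else ga[1] <- 0
  if (trail) { ta <- c(ta, t_ip1); ga <- c(ga, 0) } else ga[length(ga)] <- 0

  v <- pracma::cumtrapz(ta, ga)            # first integral of GRF_x (N s)
  D <- as.numeric(pracma::cumtrapz(ta, v)) # second integral (N s^2)

  p0 <- interp_uniform(s$cop_x, s$t0, fs, t_i)
  p1 <- interp_uniform(s$cop_x, s$t0, fs, t_ip1)

  # Newton: x (mm) = 1000 * D / m + C1 (t - t_i) + C0, pinned to COP at the ends
  base <- 1000 * D / mass
  C0 <- p0                                 # D(t_i) = 0, so x(t_i) = C0
  C1 <- (p1 - base[length(base)] - C0) / (t_ip1 - t_i)
  x_aug <- base + C1 * (ta - t_i) + C0

  keep <- seq_along(x_aug)
  if (lead) keep <- keep[-1]
  if (trail) keep <- keep[-length(keep)]
  list(idx = idx, x = x_aug[keep])
}

#' @export
print.com_trajectory <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("<com_trajectory> %d samples, %d valid (%.1f%%), %d GRF zero crossings\n",
              length(x$x), nv, 100 * nv / length(x$x), nrow(x$crossings)))
  invisible(x)
}

#' @export
summary.com_trajectory <- function(object, ...) {
  v <- object$valid
  out <- list(
    n = length(object$x),
    n_valid = sum(v),
    valid_fraction = mean(v),
    n_crossings = nrow(object$crossings),
    com_range_mm = if (any(v)) diff(range(object$x[v])) else NA_real_,
    e_x_sd_mm = if (sum(v) > 1) stats::sd(object$e_x[v]) else NA_real_,
    ipvi = ipvi(object$e_x, object$series$grf_x, object$valid))
  class(out) <- "summary.com_trajectory"
  out
}

#' @export
print.summary.com_trajectory <- function(x, ...) {
  cat(sprintf("COM reconstruction: %d/%d valid samples (%.1f%%), %d zero crossings\n",
              x$n_valid, x$n, 100 * x$valid_fraction, x$n_crossings))
  cat(sprintf("COM range %.2f mm, COP-error SD %.3f mm, IPVI %.4f\n",
              x$com_range_mm, x$e_x_sd_mm, x$ipvi))
  invisible(x)
}

#' Residuals of a COM reconstruction
#'
#' Returns the COP error `e_x = x - p_x` on valid samples (`NA` elsewhere) —
#' under the pendulum model this is the quantity proportional to the AP GRF.
#' @param object A `com_trajectory`.
#' @param ... Unused.
#' @export
residuals.com_trajectory <- function(object, ...) object$e_x

#' Plot a COM reconstruction
#'
#' Two panels: COP and reconstructed COM over time, and the COP error against
#' the AP GRF (the scatter whose Pearson correlation is the validity index).
#' @param x A `com_trajectory`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.com_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  t <- sway_times(x$series)
  graphics::plot(t, x$series$cop_x, type = "l", col = "grey50",
                 xlab = "time (s)", ylab = "AP displacement (mm)", ...)
  graphics::lines(t, x$x, col = "firebrick")
  graphics::legend("topright", c("COP", "COM (reconstructed)"),
                   col = c("grey50", "firebrick"), lty = 1, bty = "n")
  v <- x$valid
  graphics::plot(x$series$grf_x[v], x$e_x[v], pch = 16, cex = 0.3,
                 xlab = "GRF_x (N)", ylab = "COP error (mm)")
  invisible(x)
}
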
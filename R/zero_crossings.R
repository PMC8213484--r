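#' Locate zero instants of the AP ground-reaction force
#'
#' Finds every time at which `grf_x` crosses zero. At such instants the
#' pendulum model puts the COM vertically over the COP, which is what makes
#' them usable as boundary conditions for segment-wise double integration.
#' Crossings between samples are located by linear interpolation of the two
#' bracketing samples; a sample that is exactly zero is a crossing at that
#' sample time, and runs of consecutive exact zeros collapse to their first
#' sample. Crossings closer than `min_gap_s` to the previously retained
#' crossing are dropped: segments shorter than the filter's resolvable
#' timescale are noise artefacts around zero, not COM information.
#'
#' @param s A [sway_series()] (normally low-pass filtered first).
#' @param min_gap_s Minimum spacing between retained crossings (s); default
#'   0.02 s, about ten samples at 512 Hz.
#' @return An object of class `zero_crossings`: a data frame with columns
#'   `time` (interpolated zero instant, s), `i_left` and `i_right` (bracketing
#'   sample indices; equal when the zero falls exactly on a sample). Zero rows
#'   is a legal result.
#' @export
find_grf_zero_crossings <- function(s, min_gap_s = 0.02) {
  validate_sway_series(s)
  if (min_gap_s < 0) stop("`min_gap_s` must be >= 0")
  g <- s$grf_x
  t <- sway_times(s)
  n <- length(g)

  is_zero <- g == 0
  # first sample of each run of exact zeros
  zero_starts <- which(is_zero & c(TRUE, !is_zero[-n]))
  times <- t[zero_starts]
  i_left <- zero_starts
  i_right <- zero_starts

  # sign changes between adjacent nonzero-bracketing samples
  prod_sign <- g[-n] * g[-1]
  k <- which(prod_sign < 0)
  if (length(k)) {
    tc <- t[k] - g[k] * (t[k + 1] - t[k]) / (g[k + 1] - g[k])
    times <- c(times, tc)
    i_left <- c(i_left, k)
    i_right <- c(i_right, k + 1L)
  }
  o <- order(times)
  times <- times[o]; i_left <- i_left[o]; i_right <- i_right[o]

  if (length(times) > 1 && min_gap_s > 0) {
    keep <- rep(TRUE, length(times))
    last_t <- -Inf
    for (j in seq_along(times)) {
      if (times[j] - last_t < min_gap_s && is.finite(last_t)) {
        keep[j] <- FALSE
      } else {
        last_t <- times[j]
      }
    }
    times <- times[keep]; i_left <- i_left[keep]; i_right <- i_right[keep]
  }

  structure(data.frame(time = times, i_left = i_left, i_right = i_right),
            class = c("zero_crossings", "data.frame"))
}
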
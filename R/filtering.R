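#' Zero-phase Butterworth low-pass filtering
#'
#' Applies an order-`order` digital Butterworth low-pass design forward and
#' backward over every channel (effective magnitude response of order
#' `2 * order`, zero phase). Zero-phase filtering is the posturography
#' convention: a causal single pass would lag the COP relative to the force
#' channel and bias any COP/GRF correlation. As a consequence the gain at the
#' cutoff frequency is |H|^2 = 0.5 (the squared half-power point), not 1/sqrt(2).
#'
#' The filter runs as a cascade of second-order sections (one biquad per
#' analog pole pair, bilinear-transformed with frequency prewarping) rather
#' than a single direct-form transfer function: at narrow normalized cutoffs
#' such as 5 Hz / 512 Hz a 6th-order direct form loses ~7 digits to
#' coefficient cancellation, while the cascade keeps filtering linear and
#' DC-exact to near machine precision. Startup transients are suppressed by
#' odd-reflection padding of `3 * order` samples at each end plus
#' constant-steady-state initial conditions; the padding is discarded so
#' output length equals input length.
#'
#' @param s A [sway_series()].
#' @param order Filter order of the one-pass design; even, >= 2. Default 6.
#' @param cutoff_hz Cutoff frequency in Hz, strictly below Nyquist. Default 5.
#' @return A filtered [sway_series()] on the same grid.
#' @examples
#' s <- sway_series(fs = 512, cop_x = rnorm(2048), grf_x = rnorm(2048))
#' f <- butterworth_lowpass(s, order = 6, cutoff_hz = 5)
#' @export
butterworth_lowpass <- function(s, order = 6, cutoff_hz = 5) {
  validate_sway_series(s)
  if (order < 2 || order %% 2 != 0) stop("`order` must be even and >= 2")
  if (cutoff_hz <= 0 || cutoff_hz >= s$fs / 2)
    stop("`cutoff_hz` must lie strictly between 0 and the Nyquist frequency")
  n <- sway_length(s)
  if (n < 3 * order) stop("series too short for stable zero-phase filtering")
  sos <- butter_lowpass_sos(order, cutoff_hz, s$fs)
  filt <- function(y) filtfilt_sos(sos, y, pad = 3L * order)
  sway_series(fs = s$fs, t0 = s$t0,
              cop_x = filt(s$cop_x), grf_x = filt(s$grf_x),
              grf_z = if (!is.null(s$grf_z)) filt(s$grf_z))
}

# Butterworth low-pass as second-order sections. The analog prototype poles
# sit at angles phi = (2k - 1) pi / (2 order) from the negative real axis;
# each conjugate pair becomes a biquad with damping zeta = cos(phi), mapped
# to z by the prewarped bilinear transform.
butter_lowpass_sos <- function(order, cutoff_hz, fs) {
  W <- tan(pi * cutoff_hz / fs)   # prewarped analog cutoff
  lapply(seq_len(order %/% 2L), function(k) {
    zeta <- cos((2 * k - 1) * pi / (2 * order))
    a0 <- 1 + 2 * zeta * W + W^2
    list(b = W^2 * c(1, 2, 1) / a0,
         a = c(1, 2 * (W^2 - 1) / a0, (1 - 2 * zeta * W + W^2) / a0))
  })
}

# Forward-backward filtering with odd (point-reflected) edge padding: the
# signal is extended by rotating it 180 degrees about each endpoint so the
# extension is continuous in value and slope, and each biquad starts from its
# constant-input steady state (unit DC gain: previous outputs equal previous
# inputs).
filtfilt_sos <- function(sos, y, pad) {
  n <- length(y)
  pad <- min(pad, n - 1L)
  head_ext <- 2 * y[1] - y[seq(pad + 1L, 2L)]
  tail_ext <- 2 * y[n] - y[seq(n - 1L, n - pad)]
  x <- c(head_ext, y, tail_ext)
  run <- function(x) {
    for (sec in sos)
      x <- signal::filter(sec$b, sec$a, x,
                          init.x = c(x[1], x[1]), init.y = c(x[1], x[1]))
    x
  }
  out <- rev(run(rev(run(x))))
  as.numeric(out[seq(pad + 1L, pad + n)])
}
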
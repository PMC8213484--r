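#' Inverted-pendulum validity index
#'
#' The IPVI is the Pearson product-moment correlation between the COP error
#' `e_x` (COP minus the vertical COM projection, mm) and the AP
#' ground-reaction force `grf_x` (N), computed over valid paired samples.
#' When sway is well described by a single-link pendulum the two are exactly
#' proportional and the index approaches 1; multi-segment coordination breaks
#' the proportionality and lowers it. No detrending or transformation is
#' applied: the pendulum model predicts raw linear proportionality.
#'
#' @param e_x COP-error samples (mm).
#' @param grf_x AP GRF samples (N), same length.
#' @param valid Optional logical mask of samples to use (default: pairs where
#'   both channels are non-`NA`).
#' @return The correlation in `[-1, 1]`, or `NA` when fewer than 2 valid pairs
#'   remain or either channel has zero variance (undefined, never fabricated).
#' @examples
#' ipvi(c(1, 2, 3), c(10, 20, 30))  # exact proportionality -> 1
#' @export
ipvi <- function(e_x, grf_x, valid = NULL) {
  if (length(e_x) != length(grf_x)) stop("`e_x` and `grf_x` must have equal length")
  use <- if (is.null(valid)) rep(TRUE, length(e_x)) else as.logical(valid)
  use <- use & !is.na(e_x) & !is.na(grf_x)
  if (sum(use) < 2) return(NA_real_)
  a <- e_x[use]; b <- grf_x[use]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Mean AP COP velocity
#'
#' Total AP path length divided by duration: `sum(|diff(cop_x)|) / T` with
#' `T = (n - 1) / fs`. One of the most sensitive conventional COP measures of
#' postural steadiness; reported in mm/s.
#'
#' @param cop_x AP COP samples (mm).
#' @param fs Sampling rate (Hz).
#' @return Mean velocity (mm/s), >= 0.
#' @export
mv_ap <- function(cop_x, fs) {
  if (length(cop_x) < 2) stop("`cop_x` needs at least 2 samples")
  if (fs <= 0) stop("`fs` must be positive")
  sum(abs(diff(cop_x))) / ((length(cop_x) - 1) / fs)
}

#' Planar mean COP velocity
#'
#' Mean planar velocity from Euclidean step lengths, together with the
#' per-axis components.
#'
#' @param cop_x AP COP samples (mm).
#' @param cop_y ML COP samples (mm), same length.
#' @param fs Sampling rate (Hz).
#' @return A list with `mv` (planar, mm/s), `mv_ml` and `mv_ap`.
#' @export
mv_planar <- function(cop_x, cop_y, fs) {
  if (length(cop_x) != length(cop_y)) stop("`cop_x` and `cop_y` length mismatch")
  if (length(cop_x) < 2) stop("need at least 2 samples")
  T <- (length(cop_x) - 1) / fs
  list(mv = sum(sqrt(diff(cop_x)^2 + diff(cop_y)^2)) / T,
       mv_ml = sum(abs(diff(cop_y))) / T,
       mv_ap = sum(abs(diff(cop_x))) / T)
}

#' Trial-level validity-index and velocity features
#'
#' @param s The (filtered) [sway_series()] of the trial.
#' @param com The matching [estimate_com()] result.
#' @return A one-row data frame with `ipvi`, `mv_ap` (mm/s) and `n_valid`.
#' @export
trial_features <- function(s, com) {
  stopifnot(inherits(com, "com_trajectory"))
  data.frame(ipvi = ipvi(com$e_x, s$grf_x, com$valid),
             mv_ap = mv_ap(s$cop_x, s$fs),
             n_valid = sum(com$valid))
}

#' Per-window validity-index and velocity features
#'
#' Splits the trial into consecutive non-overlapping windows of `window_s`
#' seconds on the trial clock (a 30 s trial at 1 s windows gives exactly 30;
#' any trailing remainder shorter than a window is dropped) and computes the
#' features per window. The COM is reconstructed once for the whole trial and
#' only then windowed; the validity mask filters samples within each window.
#' Windows with fewer than 2 valid samples, or zero variance in either
#' channel, get an undefined (`NA`) index. `mv_ap` uses all window samples:
#' the COP is observed everywhere, regardless of COM validity.
#'
#' @param s The (filtered) [sway_series()] of the trial.
#' @param com The matching [estimate_com()] result.
#' @param window_s Window length in seconds (default 1).
#' @return A data frame with one row per window: `window_index` (0-based),
#'   `ipvi`, `mv_ap`, `n_valid`.
#' @export
windowed_features <- function(s, com, window_s = 1) {
  stopifnot(inherits(com, "com_trajectory"))
  if (window_s <= 0) stop("`window_s` must be positive")
  nper <- round(window_s * s$fs)
  if (nper < 2) stop("window too short at this sampling rate")
  nwin <- floor(sway_length(s) / nper)
  if (nwin < 1) stop("trial shorter than one window")
  rows <- lapply(seq_len(nwin) - 1L, function(w) {
    i <- (w * nper + 1L):((w + 1L) * nper)
    data.frame(window_index = w,
               ipvi = ipvi(com$e_x[i], s$grf_x[i], com$valid[i]),
               mv_ap = mv_ap(s$cop_x[i], s$fs),
               n_valid = sum(com$valid[i]))
  })
  do.call(rbind, rows)
}

#' Median split of windows by validity index
#'
#' Sorts windows with a defined index by `ipvi` in descending order (stable,
#' preserving input order among ties); the first `ceiling(n / 2)` windows form
#' the larger-IPVI half. Returns the mean `mv_ap` of each half — the quantity
#' used to test whether pendulum-like windows are also faster-swaying windows.
#'
#' @param windows A data frame from [windowed_features()] (columns `ipvi`,
#'   `mv_ap`).
#' @return Named numeric vector `c(larger = ..., smaller = ...)` (mm/s).
#' @export
ipvi_median_split <- function(windows) {
  stopifnot(is.data.frame(windows), all(c("ipvi", "mv_ap") %in% names(windows)))
  ok <- windows[!is.na(windows$ipvi), , drop = FALSE]
  n <- nrow(ok)
  if (n < 2) stop("need at least 2 windows with a defined ipvi")
  o <- order(-ok$ipvi)            # radix order is stable for ties
  n_hi <- ceiling(n / 2)
  hi <- ok$mv_ap[o[seq_len(n_hi)]]
  lo <- ok$mv_ap[o[(n_hi + 1L):n]]
  c(larger = mean(hi), smaller = mean(lo))
}
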
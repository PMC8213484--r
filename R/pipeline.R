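#' Run the full feature pipeline on one trial
#'
#' Filter, reconstruct the COM, and compute trial-level and one-second-window
#' features — the standard processing path applied to each recorded or
#' simulated trial.
#'
#' @param series A raw [sway_series()].
#' @param anthro An [anthro_model()] for the subject.
#' @param filter_order,cutoff_hz Zero-phase Butterworth settings
#'   (see [butterworth_lowpass()]); defaults 6 and 5 Hz.
#' @param min_gap_s Minimum GRF zero-crossing spacing (s).
#' @param window_s Window length for [windowed_features()] (s).
#' @return A list with `trial` (one-row data frame from [trial_features()]),
#'   `windows` (data frame from [windowed_features()]) and `com`
#'   (the `com_trajectory`).
#' @export
process_trial <- function(series, anthro, filter_order = 6, cutoff_hz = 5,
                          min_gap_s = 0.02, window_s = 1) {
  filtered <- butterworth_lowpass(series, order = filter_order,
                                  cutoff_hz = cutoff_hz)
  com <- estimate_com(filtered, anthro, min_gap_s = min_gap_s)
  list(trial = trial_features(filtered, com),
       windows = windowed_features(filtered, com, window_s = window_s),
       com = com)
}

#' Compute feature tables for a whole cohort
#'
#' Applies [process_trial()] to every trial of a [synth_cohort()] result (or
#' any equivalently shaped list), using each subject's composite mass and COM
#' height with the default point-mass inertia on the estimation side.
#'
#' @param cohort A list with `subjects`, `trials` and either `series`
#'   (in-memory) or a `file` column in `trials` (on-disk, see [read_trial()]).
#' @param ... Passed to [process_trial()].
#' @return A list of two data frames: `trials` (one row per trial: subject,
#'   group, session, trial, `ipvi`, `mv_ap`, `n_valid`) and `windows` (one row
#'   per 1 s window, with `window_index`).
#' @export
cohort_features <- function(cohort, ...) {
  trials <- cohort$trials
  n <- nrow(trials)
  trial_rows <- vector("list", n)
  window_rows <- vector("list", n)
  for (i in seq_len(n)) {
    row <- trials[i, ]
    series <- if (!is.null(cohort$series)) cohort$series[[i]]
              else read_trial(row$file)$series
    anthro <- anthro_model(row$mass_kg, row$com_height_m)
    res <- process_trial(series, anthro, ...)
    id_cols <- data.frame(subject_id = row$subject_id, group = row$group,
                          session = row$session, trial = row$trial)
    trial_rows[[i]] <- cbind(id_cols, res$trial)
    window_rows[[i]] <- cbind(id_cols[rep(1, nrow(res$windows)), , drop = FALSE],
                              res$windows)
  }
  out <- list(trials = do.call(rbind, trial_rows),
              windows = do.call(rbind, window_rows))
  rownames(out$trials) <- rownames(out$windows) <- NULL
  out
}
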
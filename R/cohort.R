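#' Specify a synthetic quiet-standing cohort
#'
#' Describes a two-group study of repeated quiet-stance trials, mirroring the
#' canonical design of 20 subjects per group, 12 trials per subject (3 trials
#' in each of 4 sessions) and 30 s of analysed signal per trial. Subjects are
#' simulated with the two-link ankle-hip model; each group is a distribution
#' over subject-level simulator parameters.
#'
#' The group parameterization is a modelling choice, not an empirical claim:
#' the older group gets a stiffer hip (more pendulum-like, raising the
#' validity index) and stronger motor noise (faster sway, raising MV_AP),
#' which emulates the direction of reported age differences without asserting
#' their magnitudes. Hip stiffness multipliers are drawn log-normally
#' (multiplicative spread `gsd`), truncated at 0.5 x ankle stiffness to stay
#' well inside the stable region; noise SDs are normal, truncated at 4 bounds.
#'
#' @param groups Named list of group specs; each a list with `n_subjects`,
#'   `hip_mult` (`c(mean, gsd)`: hip stiffness as a multiple of ankle
#'   stiffness) and `noise_sd` (`c(mean, sd)`, N m).
#' @param trials_per_subject Trials per subject (sessions of 3 are derived).
#' @param duration_s,fs Trial length (s) and sampling rate (Hz).
#' @param mass,stature_scale Population anthropometric draws: `c(mean, sd)`
#'   for total mass (kg) and for a dimensionless scale applied to segment
#'   lengths.
#' @param seed Master seed; every subject parameter and trial realization is
#'   reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = list(
                          younger = list(n_subjects = 20,
                                         hip_mult = c(mean = 1.5, gsd = 1.4),
                                         noise_sd = c(mean = 0.40, sd = 0.05)),
                          older = list(n_subjects = 20,
                                       hip_mult = c(mean = 20, gsd = 1.4),
                                       noise_sd = c(mean = 0.55, sd = 0.06))),
                        trials_per_subject = 12, duration_s = 30, fs = 512,
                        mass = c(mean = 70, sd = 10),
                        stature_scale = c(mean = 1, sd = 0.04),
                        seed = 1) {
  if (length(groups) < 1 || is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("`groups` must be a non-empty named list")
  for (gname in names(groups)) {
    gr <- groups[[gname]]
    if (is.null(gr$n_subjects) || gr$n_subjects < 1)
      stop("group '", gname, "' needs n_subjects >= 1")
    if (length(gr$hip_mult) != 2 || length(gr$noise_sd) != 2)
      stop("group '", gname, "' needs hip_mult = c(mean, gsd) and noise_sd = c(mean, sd)")
  }
  if (trials_per_subject < 1) stop("`trials_per_subject` must be >= 1")
  structure(list(groups = groups, trials_per_subject = trials_per_subject,
                 duration_s = duration_s, fs = fs, mass = mass,
                 stature_scale = stature_scale, seed = as.integer(seed)),
            class = "cohort_spec")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Draw the subject table of a cohort
#'
#' Deterministically (from the master seed) draws per-subject parameters and
#' the derived composite anthropometrics used on the estimation side.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with one row per subject: `subject_id`, `group`,
#'   `mass_kg`, `stature_scale`, `hip_mult`, `noise_sd`, `com_height_m`
#'   (composite COM height above the ankle).
#' @export
cohort_subjects <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed + 104729L, {
    rows <- lapply(names(spec$groups), function(gname) {
      gr <- spec$groups[[gname]]
      ns <- gr$n_subjects
      data.frame(
        subject_id = sprintf("%s%02d", toupper(substr(gname, 1, 1)), seq_len(ns)),
        group = gname,
        mass_kg = rtrunc_norm(ns, spec$mass[["mean"]], spec$mass[["sd"]],
                              spec$mass[["mean"]] - 3 * spec$mass[["sd"]],
                              spec$mass[["mean"]] + 3 * spec$mass[["sd"]]),
        stature_scale = rtrunc_norm(ns, spec$stature_scale[["mean"]],
                                    spec$stature_scale[["sd"]], 0.8, 1.2),
        hip_mult = pmax(stats::rlnorm(ns, log(gr$hip_mult[["mean"]]),
                                      log(gr$hip_mult[["gsd"]])), 0.5),
        noise_sd = rtrunc_norm(ns, gr$noise_sd[["mean"]], gr$noise_sd[["sd"]],
                               0.05, gr$noise_sd[["mean"]] + 4 * gr$noise_sd[["sd"]]))
    })
    subjects <- do.call(rbind, rows)
    cfgs <- lapply(seq_len(nrow(subjects)), function(i)
      subject_dl_config(subjects[i, ], spec, seed = 0L))
    subjects$com_height_m <- vapply(cfgs, function(cf) composite_anthro(cf)$h, 0)
    subjects
  })
}

# Two-link config for one subject row; segment masses/lengths scale with the
# subject's mass and stature draws.
subject_dl_config <- function(subj, spec, seed) {
  sc <- subj$stature_scale
  lower <- list(mass = 0.32 * subj$mass_kg, length = 0.85 * sc,
                com_offset = 0.45 * sc)
  upper <- list(mass = 0.68 * subj$mass_kg, length = 0.75 * sc,
                com_offset = 0.32 * sc)
  g1g2 <- (lower$mass * lower$com_offset + upper$mass * lower$length +
             upper$mass * upper$com_offset) * 9.81
  k_ankle <- 1.2 * g1g2
  double_link_config(lower = lower, upper = upper, k_ankle = k_ankle,
                     k_hip = subj$hip_mult * k_ankle,
                     ankle_noise_sd = subj$noise_sd,
                     duration_s = spec$duration_s, fs = spec$fs, seed = seed)
}

#' Enumerate the trials of a cohort without simulating them
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with one row per (subject, trial): subject columns
#'   plus `session` (groups of 3 trials), `trial` (within session), and the
#'   derived per-trial `seed`.
#' @export
cohort_trial_table <- function(spec) {
  subjects <- cohort_subjects(spec)
  k <- spec$trials_per_subject
  tab <- subjects[rep(seq_len(nrow(subjects)), each = k), , drop = FALSE]
  idx <- rep(seq_len(k), nrow(subjects))
  tab$session <- (idx - 1L) %/% 3L + 1L
  tab$trial <- (idx - 1L) %% 3L + 1L
  tab$seed <- (spec$seed %% 100003L) * 20011L + seq_len(nrow(tab)) * 7919L
  rownames(tab) <- NULL
  tab
}

#' Simulate a synthetic cohort
#'
#' Simulates every trial of the cohort with the two-link model and returns (or
#' writes) the force-plate series with populated metadata. Rerunning with the
#' same spec and master seed reproduces the cohort exactly.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional directory: when given, each trial is written with
#'   [write_trial()] (files `trial_<subject>_s<session>_t<trial>.csv`) along
#'   with a `subjects.csv` manifest, and file paths are returned in the trial
#'   table.
#' @param progress Logical; print a dot per simulated subject.
#' @return A list with `subjects` (see [cohort_subjects()]), `trials` (the
#'   [cohort_trial_table()], plus `file` when writing) and, when `dir` is
#'   `NULL`, `series` (list of [sway_series()], one per trial row).
#' @export
synth_cohort <- function(spec, dir = NULL, progress = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- cohort_subjects(spec)
  trials <- cohort_trial_table(spec)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  series_list <- if (is.null(dir)) vector("list", nrow(trials))
  files <- character(nrow(trials))
  last_subj <- ""
  for (i in seq_len(nrow(trials))) {
    row <- trials[i, ]
    cfg <- subject_dl_config(row, spec, seed = row$seed)
    sim <- simulate_double_link(cfg)
    if (progress && row$subject_id != last_subj) {
      cat("."); utils::flush.console(); last_subj <- row$subject_id
    }
    if (is.null(dir)) {
      series_list[[i]] <- sim$series
    } else {
      meta <- trial_meta(subject_id = row$subject_id, group = row$group,
                        session = row$session, trial = row$trial)
      files[i] <- file.path(dir, sprintf("trial_%s_s%d_t%d.csv",
                                         row$subject_id, row$session, row$trial))
      write_trial(sim$series, meta, files[i])
    }
  }
  if (progress) cat("\n")
  if (!is.null(dir)) {
    utils::write.csv(subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
    trials$file <- files
    list(subjects = subjects, trials = trials)
  } else {
    list(subjects = subjects, trials = trials, series = series_list)
  }
}
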
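#' Per-subject trial means
#'
#' Averages a per-trial feature over each subject's trials — the reliability
#' device of repeated-measures posturography (e.g. the mean of 12 trials as
#' one sample per subject).
#'
#' @param df Data frame with columns `subject_id`, `group`, `value`.
#' @return Data frame with one row per subject: `subject_id`, `group`,
#'   `value` (mean), `n_trials_averaged`.
#' @export
subject_means <- function(df) {
  stopifnot(all(c("subject_id", "group", "value") %in% names(df)))
  if (anyNA(df$value)) stop("per-trial values must not be NA")
  if (nrow(df) == 0) stop("no trial values supplied")
  split_by <- interaction(df$subject_id, df$group, drop = TRUE)
  parts <- split(df, split_by)
  out <- do.call(rbind, lapply(parts, function(p)
    data.frame(subject_id = p$subject_id[1], group = p$group[1],
               value = mean(p$value), n_trials_averaged = nrow(p))))
  rownames(out) <- NULL
  out[order(out$group, out$subject_id), , drop = FALSE]
}

#' All k-subset trial averages
#'
#' Enumerates every unordered k-subset of the trial values in lexicographic
#' order and returns the subset means. Averaging 3 of 12 trials turns 12
#' measurements into choose(12, 3) = 220 samples per subject — the dataset
#' inflation used for single-feature classification.
#'
#' @param values Numeric vector of per-trial values.
#' @param k Subset size, `1 <= k <= length(values)`.
#' @return Numeric vector of length `choose(length(values), k)`.
#' @export
trial_average_samples <- function(values, k) {
  n <- length(values)
  if (k < 1 || k > n) stop("`k` must be between 1 and length(values)")
  colMeans(matrix(values[utils::combn(n, k)], nrow = k))
}

#' Independent two-sample Student's t-test
#'
#' Equal-variance (pooled) two-sided t-test with
#' `df = n_a + n_b - 2` — the classical independent Student's test, as opposed
#' to Welch's unequal-variance variant.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return List with `t`, `p` (two-sided) and `df`.
#' @export
independent_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero pooled variance: t statistic undefined")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with midrank tie correction: tied
#' positive-negative score pairs contribute 1/2. Orientation is fixed: a
#' higher score argues for the positive class.
#'
#' @param scores Numeric scores.
#' @param labels Class labels; coerced by `labels == positive`.
#' @param positive The positive-class label (default `"older"`).
#' @return The AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = "older") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks: ties count 1/2 in the pair tally
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification accuracy at the best threshold
#'
#' Scans candidate thresholds at the midpoints between consecutive distinct
#' sorted scores, plus the two boundary thresholds outside the score range
#' (the all-one-class rules), in both orientations (score above threshold
#' positive, or below), and returns the maximum resubstitution accuracy.
#' Ties are broken toward the lower threshold, preferring the `>` orientation.
#'
#' @inheritParams roc_auc
#' @return List with `accuracy`, `threshold` and `direction` (`">"` means
#'   scores above the threshold are classified positive).
#' @export
accuracy_at_best_threshold <- function(scores, labels, positive = "older") {
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  su <- sort(unique(scores))
  half_step <- if (length(su) > 1) min(diff(su)) / 2 else 1
  thr <- c(su[1] - half_step,
           if (length(su) > 1) (su[-1] + su[-length(su)]) / 2,
           su[length(su)] + half_step)
  best <- list(accuracy = -Inf, threshold = NA_real_, direction = ">")
  for (dir in c(">", "<")) {
    for (th in thr) {
      pred <- if (dir == ">") scores > th else scores < th
      acc <- mean(pred == pos)
      if (acc > best$accuracy + 1e-12)
        best <- list(accuracy = acc, threshold = th, direction = dir)
    }
  }
  best
}

#' Two-group comparison report
#'
#' Runs the full statistical battery on cohort feature tables:
#' \describe{
#'   \item{feature_comparison}{Per feature (`ipvi`, `mv_ap`): group means and
#'     SDs of the per-subject trial averages, with the independent Student's
#'     t-test p-value.}
#'   \item{median_split}{Per group: each subject's 1 s windows are median-split
#'     by validity index; the subject's mean `mv_ap` over the larger-IPVI and
#'     smaller-IPVI halves form two samples compared by independent t-test.}
#'   \item{classification}{Per feature: every subject contributes all
#'     3-of-n trial-average samples (resubstitution, no held-out set); AUC by
#'     the rank formulation and accuracy at the best single threshold.}
#' }
#'
#' @param features A list with data frames `trials` and `windows` as returned
#'   by [cohort_features()].
#' @param groups Character vector of length 2: the (negative, positive) group
#'   labels; default `c("younger", "older")`.
#' @param k Trial-subset size for classification samples (default 3).
#' @return An object of class `ipvi_report` (a list of the three tables).
#' @export
run_group_comparison <- function(features, groups = c("younger", "older"), k = 3) {
  trials <- features$trials
  windows <- features$windows
  stopifnot(length(groups) == 2)
  trials <- trials[trials$group %in% groups, , drop = FALSE]
  windows <- windows[windows$group %in% groups, , drop = FALSE]
  if (length(unique(trials$group)) < 2)
    stop("two groups required: found ", paste(unique(trials$group), collapse = ", "))
  n_subj <- table(unique(trials[c("subject_id", "group")])$group)
  if (any(n_subj < 2)) stop("each group needs at least 2 subjects")

  feats <- c("ipvi", "mv_ap")

  # feature comparison on per-subject trial means
  fc <- do.call(rbind, lapply(feats, function(f) {
    sm <- subject_means(data.frame(subject_id = trials$subject_id,
                                   group = trials$group, value = trials[[f]]))
    a <- sm$value[sm$group == groups[1]]
    b <- sm$value[sm$group == groups[2]]
    tt <- independent_t_test(b, a)
    data.frame(feature = f,
               mean_1 = mean(a), sd_1 = stats::sd(a),
               mean_2 = mean(b), sd_2 = stats::sd(b),
               t = tt$t, df = tt$df, p = tt$p)
  }))
  names(fc) <- sub("_1$", paste0("_", groups[1]), names(fc))
  names(fc) <- sub("_2$", paste0("_", groups[2]), names(fc))

  # within-group median split of windows by IPVI
  ms <- do.call(rbind, lapply(groups, function(g) {
    wg <- windows[windows$group == g, , drop = FALSE]
    per_subj <- lapply(split(wg, wg$subject_id, drop = TRUE), ipvi_median_split)
    larger <- vapply(per_subj, `[[`, 0, "larger")
    smaller <- vapply(per_subj, `[[`, 0, "smaller")
    tt <- independent_t_test(larger, smaller)
    data.frame(group = g,
               mean_larger = mean(larger), sd_larger = stats::sd(larger),
               mean_smaller = mean(smaller), sd_smaller = stats::sd(smaller),
               t = tt$t, df = tt$df, p = tt$p)
  }))

  # single-feature classification on k-trial-average samples
  cl <- do.call(rbind, lapply(feats, function(f) {
    samp <- do.call(rbind, lapply(split(trials, trials$subject_id, drop = TRUE),
      function(tr) data.frame(group = tr$group[1],
                              score = trial_average_samples(tr[[f]], k))))
    auc <- roc_auc(samp$score, samp$group, positive = groups[2])
    acc <- accuracy_at_best_threshold(samp$score, samp$group, positive = groups[2])
    data.frame(feature = f, n_samples = nrow(samp), auc = auc,
               accuracy = acc$accuracy, threshold = acc$threshold,
               direction = acc$direction)
  }))
  rownames(fc) <- rownames(ms) <- rownames(cl) <- NULL

  structure(list(feature_comparison = fc, median_split = ms,
                 classification = cl, groups = groups, k = k),
            class = "ipvi_report")
}

#' @export
print.ipvi_report <- function(x, digits = 4, ...) {
  cat("Two-group quiet-standing comparison (", x$groups[1], " vs ",
      x$groups[2], ")\n\n", sep = "")
  cat("Per-subject trial-mean features:\n")
  print(format_df_num(x$feature_comparison, digits))
  cat("\nWithin-group median split of 1 s windows by IPVI (mean MV_AP, mm/s):\n")
  print(format_df_num(x$median_split, digits))
  cat(sprintf("\nSingle-feature classification on %d-trial-average samples:\n", x$k))
  print(format_df_num(x$classification, digits))
  invisible(x)
}

format_df_num <- function(df, digits) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}
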
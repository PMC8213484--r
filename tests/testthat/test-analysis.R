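test_that("subject means average each subject's trials", {
  df <- data.frame(subject_id = rep(c("a", "b"), each = 12),
                   group = rep(c("younger", "older"), each = 12),
                   value = c(rep(7, 12), 1:12))
  sm <- subject_means(df)
  expect_equal(sm$value[sm$subject_id == "a"], 7)
  expect_equal(sm$value[sm$subject_id == "b"], 6.5)
  expect_equal(sm$n_trials_averaged, c(12, 12))
  expect_error(subject_means(df[0, ]), "no trial values")
})

test_that("k-subset averaging enumerates the binomial number of samples", {
  v <- rnorm(12)
  s3 <- trial_average_samples(v, 3)
  expect_length(s3, 220)
  expect_equal(trial_average_samples(v, 1), v)
  expect_equal(trial_average_samples(v, 12), mean(v))
  expect_error(trial_average_samples(v, 13), "between")
  expect_error(trial_average_samples(v, 0), "between")
  # count identity and the combinatorial mean-of-means identity
  set.seed(31)
  for (n in c(2, 5, 9, 12)) {
    vals <- rnorm(n)
    for (k in seq_len(n)) {
      s <- trial_average_samples(vals, k)
      expect_length(s, choose(n, k))
      expect_equal(mean(s), mean(vals), tolerance = 1e-12)
    }
  }
  # lexicographic order: first sample is the mean of the first k values
  expect_equal(s3[1], mean(v[1:3]))
})

test_that("the pooled t-test matches the closed formula and its invariances", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  got <- independent_t_test(a, b)
  ref <- t_test_formula(a, b)
  expect_equal(got$t, ref$t, tolerance = 1e-10)
  expect_equal(got$p, ref$p, tolerance = 1e-10)
  expect_equal(got$df, 8)

  same <- independent_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  shifted <- independent_t_test(a + 100, b + 100)
  expect_equal(shifted$t, got$t, tolerance = 1e-12)
  expect_equal(shifted$p, got$p, tolerance = 1e-12)

  expect_error(independent_t_test(1, c(1, 2)), "n >= 2")
  expect_error(independent_t_test(c(2, 2), c(2, 2)), "zero pooled variance")
})

test_that("rank-based AUC matches pair counting, including ties", {
  lab <- c("y", "y", "o", "o")
  expect_equal(roc_auc(c(1, 2, 3, 4), lab, positive = "o"), 1)
  expect_equal(roc_auc(c(2, 2, 2, 2), lab, positive = "o"), 0.5)
  sc <- c(0.1, 0.4, 0.35, 0.8)
  expect_equal(roc_auc(sc, lab, positive = "o"),
               auc_pair_count(sc, lab, positive = "o"))
  set.seed(17)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    labels <- c("o", "y", sample(c("o", "y"), n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels, positive = "o"),
                 auc_pair_count(scores, labels, positive = "o"),
                 tolerance = 1e-12)
    # label flip symmetry is exact
    expect_equal(roc_auc(scores, labels, positive = "y"),
                 1 - roc_auc(scores, labels, positive = "o"),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c("o", "o", "o"), positive = "o"), "both classes")
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- rnorm(60)
  labels <- rep(c("y", "o"), 30)
  scores[labels == "o"] <- scores[labels == "o"] + 0.8
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("y", "o"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, labels, positive = "o"), ref, tolerance = 1e-12)
})

test_that("best-threshold accuracy matches exhaustive enumeration", {
  lab <- c("y", "y", "o", "o")
  perfect <- accuracy_at_best_threshold(c(1, 2, 5, 6), lab, positive = "o")
  expect_equal(perfect$accuracy, 1)
  expect_true(perfect$threshold > 2 && perfect$threshold < 5)
  two <- accuracy_at_best_threshold(c(3, 7), c("y", "o"), positive = "o")
  expect_equal(two$accuracy, 1)

  set.seed(77)
  scores <- rnorm(1000)
  labels <- rep(c("o", "y"), 500)   # independent of the scores
  got <- accuracy_at_best_threshold(scores, labels, positive = "o")
  expect_equal(got$accuracy, accuracy_exhaustive(scores, labels, positive = "o"))
  expect_lte(got$accuracy, 0.56)

  for (i in 1:15) {
    n <- sample(4:15, 1)
    scores <- sample(seq(0, 1, by = 0.2), n, replace = TRUE)
    labels <- c("o", "y", sample(c("o", "y"), n - 2, replace = TRUE))
    expect_equal(accuracy_at_best_threshold(scores, labels, "o")$accuracy,
                 accuracy_exhaustive(scores, labels, "o"))
  }
})

make_toy_features <- function(ipvi_o, ipvi_y, mv_o, mv_y, n_trials = 4) {
  subj <- function(id, g, iv, mv) {
    tr <- data.frame(subject_id = id, group = g, session = 1,
                     trial = seq_len(n_trials),
                     ipvi = iv + seq_len(n_trials) * 1e-3,
                     mv_ap = mv + seq_len(n_trials) * 1e-2, n_valid = 100)
    w <- data.frame(subject_id = id, group = g, session = 1,
                    trial = rep(seq_len(n_trials), each = 4),
                    window_index = rep(0:3, n_trials),
                    ipvi = iv + rnorm(4 * n_trials, 0, 0.01),
                    mv_ap = mv + rnorm(4 * n_trials, 0, 0.1), n_valid = 25)
    list(trials = tr, windows = w)
  }
  parts <- list(subj("y1", "younger", ipvi_y, mv_y),
                subj("y2", "younger", ipvi_y + 0.01, mv_y + 0.1),
                subj("o1", "older", ipvi_o, mv_o),
                subj("o2", "older", ipvi_o + 0.01, mv_o + 0.1))
  list(trials = do.call(rbind, lapply(parts, `[[`, "trials")),
       windows = do.call(rbind, lapply(parts, `[[`, "windows")))
}

test_that("forced group separation yields significant tests and a perfect AUC", {
  set.seed(5)
  fx <- make_toy_features(ipvi_o = 0.95, ipvi_y = 0.80, mv_o = 8, mv_y = 5)
  rep <- run_group_comparison(fx, k = 3)
  ipvi_row <- rep$feature_comparison[rep$feature_comparison$feature == "ipvi", ]
  expect_lt(ipvi_row$p, 0.05)
  expect_gt(ipvi_row$mean_older, ipvi_row$mean_younger)
  expect_equal(rep$classification$auc[rep$classification$feature == "ipvi"], 1)
  expect_equal(rep$classification$n_samples, c(16, 16))  # 4 subjects x C(4,3)
})

test_that("identical groups give null statistics", {
  set.seed(6)
  fx <- make_toy_features(ipvi_o = 0.9, ipvi_y = 0.9, mv_o = 6, mv_y = 6)
  # make the older group an exact copy of the younger group
  fx$trials[fx$trials$group == "older", c("ipvi", "mv_ap")] <-
    fx$trials[fx$trials$group == "younger", c("ipvi", "mv_ap")]
  rep <- run_group_comparison(fx, k = 3)
  expect_equal(rep$feature_comparison$t, c(0, 0), tolerance = 1e-12)
  expect_equal(rep$feature_comparison$p, c(1, 1), tolerance = 1e-12)
  expect_equal(rep$classification$auc, c(0.5, 0.5))
})

test_that("group comparison demands two groups of at least two subjects", {
  fx <- make_toy_features(0.9, 0.8, 7, 5)
  solo <- list(trials = fx$trials[fx$trials$group == "older", ],
               windows = fx$windows[fx$windows$group == "older", ])
  expect_error(run_group_comparison(solo), "two groups")
})
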
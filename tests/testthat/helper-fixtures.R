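# Shared fixtures and independent oracles, built in code at test time.

default_anthro <- function() anthro_model(70, 0.9)

# Pendulum-consistent sinusoidal trial with known COM: x*(t) = amp * sin(2 pi f t)
# mm, grf_x = m * x..* (N), COP from the pendulum identity. Ground truth is exact.
make_analytic_trial <- function(fs = 512, duration_s = 30, freq = 0.4, amp = 10,
                                anthro = default_anthro()) {
  t <- seq(0, duration_s, by = 1 / fs)
  x_true <- amp * sin(2 * pi * freq * t)
  ddx <- -(2 * pi * freq)^2 * x_true             # mm/s^2
  grf <- anthro$m * ddx / 1000                   # N
  cop <- x_true - 1000 * anthro$c2 * grf         # mm
  list(series = sway_series(fs, cop_x = cop, grf_x = grf),
       x_true = x_true, t = t, anthro = anthro)
}

# Steady-state amplitude of a sinusoid in the middle third of a signal
mid_amplitude <- function(y) {
  n <- length(y)
  mid <- y[seq(floor(n / 3), floor(2 * n / 3))]
  (max(mid) - min(mid)) / 2
}

# Brute-force zero-crossing oracle: scan every adjacent sample pair for a sign
# change (plus exact zeros) and interpolate linearly. No gap merging.
brute_crossings <- function(series) {
  g <- series$grf_x
  t <- sway_times(series)
  out <- numeric(0)
  prev_zero <- FALSE
  for (k in seq_along(g)) {
    if (g[k] == 0) {
      if (!prev_zero) out <- c(out, t[k])
      prev_zero <- TRUE
    } else {
      prev_zero <- FALSE
      if (k > 1 && g[k - 1] != 0 && sign(g[k]) != sign(g[k - 1]))
        out <- c(out, t[k - 1] - g[k - 1] * (t[k] - t[k - 1]) / (g[k] - g[k - 1]))
    }
  }
  sort(out)
}

# Pair-counting AUC oracle: concordant pairs + half the ties over all
# positive-negative pairs.
auc_pair_count <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tally <- 0
  for (p in pos) for (q in neg)
    tally <- tally + (p > q) + 0.5 * (p == q)
  tally / (length(pos) * length(neg))
}

# From-scratch pooled-variance Student's t-test
t_test_formula <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tt, p = 2 * pt(-abs(tt), df), df = df)
}

# Exhaustive best-threshold oracle: every midpoint plus outside-the-range
# thresholds, both orientations.
accuracy_exhaustive <- function(scores, labels, positive) {
  pos <- labels == positive
  su <- sort(unique(scores))
  cand <- c(su[1] - 1, (su[-1] + su[-length(su)]) / 2, su[length(su)] + 1)
  best <- -Inf
  for (dir in c(">", "<")) for (th in cand) {
    pred <- if (dir == ">") scores > th else scores < th
    best <- max(best, mean(pred == pos))
  }
  best
}

# Small fast cohort spec used by pipeline-level tests
tiny_cohort_spec <- function(seed = 11, fs = 128, duration_s = 6,
                             trials_per_subject = 3, n_subjects = 2) {
  cohort_spec(groups = list(
                younger = list(n_subjects = n_subjects,
                               hip_mult = c(mean = 1.5, gsd = 1.4),
                               noise_sd = c(mean = 0.40, sd = 0.05)),
                older = list(n_subjects = n_subjects,
                             hip_mult = c(mean = 20, gsd = 1.4),
                             noise_sd = c(mean = 0.55, sd = 0.06))),
              trials_per_subject = trials_per_subject,
              duration_s = duration_s, fs = fs, seed = seed)
}
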
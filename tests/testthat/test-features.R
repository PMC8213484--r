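test_that("ipvi matches the covariance formula and behaves at the extremes", {
  g <- c(-2, 0.5, 1, 3, -1)
  expect_equal(ipvi(0.003 * g, g), 1)
  expect_equal(ipvi(-g, g), -1)

  set.seed(99)
  e <- rnorm(1000); g2 <- rnorm(1000)
  direct <- sum((e - mean(e)) * (g2 - mean(g2))) /
    sqrt(sum((e - mean(e))^2) * sum((g2 - mean(g2))^2))
  expect_equal(ipvi(e, g2), direct, tolerance = 1e-12)
  expect_lt(abs(ipvi(e, g2)), 0.15)
})

test_that("ipvi is undefined (not fabricated) for degenerate input", {
  expect_true(is.na(ipvi(rep(1, 5), 1:5)))
  expect_true(is.na(ipvi(1:5, rep(2, 5))))
  expect_true(is.na(ipvi(1:5, 1:5, valid = c(TRUE, rep(FALSE, 4)))))
})

test_that("ipvi is invariant to positive affine maps and flips sign on negation", {
  set.seed(3)
  e <- rnorm(200); g <- 0.5 * e + rnorm(200)
  r <- ipvi(e, g)
  expect_equal(ipvi(5 * e + 2, g), r, tolerance = 1e-12)
  expect_equal(ipvi(e, 0.1 * g - 7), r, tolerance = 1e-12)
  expect_equal(ipvi(-e, g), -r, tolerance = 1e-12)
})

test_that("mean AP velocity equals path length over duration", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  expect_equal(mv_ap(3 * t, fs), 3, tolerance = 1e-12)
  expect_equal(mv_ap(rep(5, 100), fs), 0)
  # triangle wave, amplitude a, period p: speed is constant 4 a / p
  a <- 2; p <- 0.5
  tri <- a * (2 * abs(2 * ((t / p) %% 1) - 1) - 1)
  expect_equal(mv_ap(tri, fs), 4 * a / p, tolerance = 1e-9)
  # invariances: time reversal, offset; linear amplitude scaling
  set.seed(8); y <- cumsum(rnorm(500))
  expect_equal(mv_ap(rev(y), fs), mv_ap(y, fs))
  expect_equal(mv_ap(y + 100, fs), mv_ap(y, fs))
  expect_equal(mv_ap(2.5 * y, fs), 2.5 * mv_ap(y, fs))
})

test_that("planar velocity decomposes over axes and handles circular paths", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  y <- sin(t)
  ap_only <- mv_planar(y, rep(0, length(t)), fs)
  expect_equal(ap_only$mv, ap_only$mv_ap)
  expect_equal(ap_only$mv_ml, 0)
  ml_only <- mv_planar(rep(0, length(t)), y, fs)
  expect_equal(ml_only$mv, ml_only$mv_ml)
  expect_equal(ml_only$mv_ap, 0)
  # unit-speed circle: planar speed 1, each axis mean |cos| = 2/pi
  fs2 <- 1000
  tc <- seq(0, 2 * pi, by = 1 / fs2)
  circ <- mv_planar(cos(tc), sin(tc), fs2)
  expect_equal(circ$mv, 1, tolerance = 1e-3)
  expect_equal(circ$mv_ap, 2 / pi, tolerance = 1e-3)
  expect_equal(circ$mv_ml, 2 / pi, tolerance = 1e-3)
  expect_error(mv_planar(1:5, 1:4, fs), "mismatch")
})

test_that("a 30 s trial yields 30 one-second windows and 12 trials yield 360", {
  fx <- make_analytic_trial(duration_s = 30)
  com <- estimate_com(fx$series, fx$anthro)
  w <- windowed_features(fx$series, com, window_s = 1)
  expect_equal(nrow(w), 30)
  expect_equal(w$window_index, 0:29)
  expect_equal(nrow(w) * 12, 360)
})

test_that("windows without valid samples have undefined ipvi but keep their slot", {
  fx <- make_analytic_trial(duration_s = 10, freq = 0.4)
  com <- estimate_com(fx$series, fx$anthro)
  # invalidate one window by force
  com$valid[(5 * 512 + 1):(6 * 512)] <- FALSE
  w <- windowed_features(fx$series, com, window_s = 1)
  expect_equal(nrow(w), 10)
  expect_true(is.na(w$ipvi[w$window_index == 5]))
  expect_false(is.na(w$mv_ap[w$window_index == 5]))
})

test_that("median split by ipvi follows the descending ceiling rule", {
  w <- data.frame(ipvi = c(0.9, 0.8, 0.7, 0.6), mv_ap = c(4, 3, 2, 1))
  expect_equal(ipvi_median_split(w), c(larger = 3.5, smaller = 1.5))
  # odd count: larger half takes the ceiling
  w5 <- data.frame(ipvi = c(0.5, 0.9, 0.3, 0.7, 0.1), mv_ap = c(3, 1, 4, 2, 5))
  expect_equal(ipvi_median_split(w5), c(larger = 2, smaller = 4.5))
  # ties: stable input order decides membership
  wt <- data.frame(ipvi = rep(0.5, 4), mv_ap = c(10, 20, 30, 40))
  expect_equal(ipvi_median_split(wt), c(larger = 15, smaller = 35))
  # undefined windows are excluded before splitting
  wna <- data.frame(ipvi = c(0.9, NA, 0.1), mv_ap = c(7, 100, 3))
  expect_equal(ipvi_median_split(wna), c(larger = 7, smaller = 3))
  expect_error(ipvi_median_split(data.frame(ipvi = 0.5, mv_ap = 1)), "at least 2")
})
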
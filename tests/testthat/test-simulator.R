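test_that("the noiseless upright pendulum stays at equilibrium", {
  sim <- simulate_ip(ip_sim_config(noise_sd = 0, theta0 = 0, duration_s = 5, seed = 1))
  expect_true(all(sim$series$cop_x == 0))
  expect_true(all(sim$series$grf_x == 0))
  expect_true(all(sim$truth_com_x == 0))
})

test_that("an overdamped lean decays monotonically and satisfies the model identity", {
  a <- default_anthro()
  mgh <- a$m * a$g * a$h
  kp <- 1.5 * mgh
  kd <- 3 * sqrt((kp - mgh) * a$I_a)   # damping ratio 1.5: overdamped
  sim <- simulate_ip(ip_sim_config(anthro = a, kp = kp, kd = kd, noise_sd = 0,
                                   theta0 = 0.02, duration_s = 10, seed = 1))
  th <- sim$truth_joint_angles[, "ankle"]
  expect_true(all(diff(th) < 1e-15))
  expect_lt(th[length(th)], 1e-3)
  # COP error = c2 * GRF_x, relative residual below 1e-6
  e <- sim$truth_com_x - sim$series$cop_x
  pred <- 1000 * a$c2 * sim$series$grf_x
  expect_lt(max(abs(e - pred)) / max(abs(e)), 1e-6)
})

test_that("a sub-toppling ankle stiffness ends in a detected fall", {
  a <- default_anthro()
  expect_warning(cfg <- ip_sim_config(anthro = a, kp = 0.9 * a$m * a$g * a$h,
                                      kd = 40, noise_sd = 0, theta0 = 0.02,
                                      duration_s = 10, seed = 1),
                 "unstable")
  expect_error(simulate_ip(cfg), class = "ipvi_fall")
})

test_that("simulations are deterministic for a fixed seed", {
  s1 <- simulate_ip(ip_sim_config(seed = 5, duration_s = 5))
  s2 <- simulate_ip(ip_sim_config(seed = 5, duration_s = 5))
  expect_identical(s1$series$cop_x, s2$series$cop_x)
  expect_identical(s1$truth_com_x, s2$truth_com_x)
  s3 <- simulate_ip(ip_sim_config(seed = 6, duration_s = 5))
  expect_false(identical(s1$series$cop_x, s3$series$cop_x))
})

test_that("the pendulum identity holds on every seeded run", {
  for (seed in 1:5) {
    sim <- simulate_ip(ip_sim_config(seed = seed, duration_s = 10))
    e <- sim$truth_com_x - sim$series$cop_x
    expect_gte(cor(e, sim$series$grf_x), 0.999)
  }
})

test_that("simulated GRF equals total mass times COM acceleration", {
  sim <- simulate_ip(ip_sim_config(seed = 2, duration_s = 5))
  fs <- sim$series$fs
  x <- sim$truth_com_x / 1000           # m
  n <- length(x)
  ddx_fd <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) * fs^2
  grf_mid <- sim$series$grf_x[2:(n - 1)]
  m <- sim$config$anthro$m
  expect_equal(grf_mid, m * ddx_fd, tolerance = 1e-3)
})

test_that("a rigid hip reproduces the composite single pendulum exactly", {
  cfg <- double_link_config(seed = 9, duration_s = 5)
  locked <- simulate_double_link(cfg, hip_locked = TRUE)
  comp <- composite_anthro(cfg)
  ip <- simulate_ip(ip_sim_config(anthro = comp, kp = cfg$k_ankle,
                                  kd = cfg$c_ankle, noise_sd = cfg$ankle_noise_sd,
                                  noise_cutoff_hz = cfg$noise_cutoff_hz,
                                  duration_s = cfg$duration_s, fs = cfg$fs,
                                  seed = cfg$seed))
  expect_equal(locked$truth_com_x, ip$truth_com_x, tolerance = 1e-8)
  expect_equal(locked$series$cop_x, ip$series$cop_x, tolerance = 1e-8)
  expect_equal(locked$series$grf_x, ip$series$grf_x, tolerance = 1e-8)
  expect_equal(locked$truth_joint_angles[, "ankle"],
               locked$truth_joint_angles[, "hip"])
})

test_that("a very stiff hip converges to the matched single-link run", {
  cfg <- double_link_config(k_hip = 1e4 * 774, seed = 13, duration_s = 10)
  dl <- simulate_double_link(cfg)
  comp <- composite_anthro(cfg)
  ip <- simulate_ip(ip_sim_config(anthro = comp, kp = cfg$k_ankle,
                                  kd = cfg$c_ankle, noise_sd = cfg$ankle_noise_sd,
                                  noise_cutoff_hz = cfg$noise_cutoff_hz,
                                  duration_s = cfg$duration_s, fs = cfg$fs,
                                  seed = cfg$seed))
  rms <- sqrt(mean((dl$truth_com_x - ip$truth_com_x)^2))
  expect_lt(rms / diff(range(ip$truth_com_x)), 0.02)
})

test_that("the quiescent two-link model stays at equilibrium and instability is caught", {
  cfg <- double_link_config(ankle_noise_sd = 0, hip_noise_sd = 0,
                            seed = 1, duration_s = 3)
  sim <- simulate_double_link(cfg)
  expect_true(all(sim$series$cop_x == 0))
  expect_true(all(sim$truth_com_x == 0))
  expect_error(double_link_config(k_ankle = 100), "unstable")
})

test_that("cohort generation enumerates and reproduces trials deterministically", {
  spec <- tiny_cohort_spec()
  tab <- cohort_trial_table(spec)
  expect_equal(nrow(tab), 2 * 2 * 3)   # groups x subjects x trials
  expect_equal(sort(unique(tab$group)), c("older", "younger"))
  expect_true(all(tab$session >= 1 & tab$trial >= 1))
  expect_true(all(tab$seed > 0 & tab$seed < 2^31))

  co1 <- synth_cohort(spec)
  co2 <- synth_cohort(spec)
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(lapply(co1$series, `[[`, "cop_x"),
                   lapply(co2$series, `[[`, "cop_x"))

  dir <- withr::local_tempdir()
  res <- synth_cohort(spec, dir = dir)
  expect_equal(length(list.files(dir, pattern = "^trial_")), 12)
  expect_true(file.exists(file.path(dir, "subjects.csv")))
  # written trials match the in-memory realization bit for bit
  got <- read_trial(res$trials$file[1])
  expect_identical(got$series$cop_x, co1$series[[1]]$cop_x)
})
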
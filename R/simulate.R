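#' Configuration for the single-link quiet-stance simulator
#'
#' The simulator integrates the linearized single-link (ankle) inverted
#' pendulum `I_a * theta.. = m g h * theta - tau` stabilized by a
#' proportional-derivative ankle torque with additive low-pass-filtered
#' Gaussian motor noise: `tau = kp * theta + kd * theta. + eta(t)`.
#' The linearized model is used throughout because it is exactly the model
#' whose validity the index quantifies: on its trajectories the identity
#' `x - p_x = I_a/(m g h) * x..` holds to integrator precision, giving the
#' pipeline a ground-truth oracle.
#'
#' Static stability requires `kp` above the gravitational toppling stiffness
#' `m g h`; a configuration below it is accepted with a warning (simulations
#' from it end in a detected fall).
#'
#' @param anthro An [anthro_model()]; default 70 kg, COM 0.9 m above ankle.
#' @param kp Ankle proportional stiffness (N m/rad); default `1.2 * m g h`.
#' @param kd Ankle damping (N m s/rad); default gives damping ratio 0.3 about
#'   the upright equilibrium.
#' @param noise_sd Stationary SD of the filtered motor-noise torque (N m);
#'   default 0.4.
#' @param noise_cutoff_hz Noise bandwidth: white Gaussian torque noise is
#'   shaped by a 2nd-order low-pass at this cutoff (Hz); default 2, which
#'   produces realistic 0.1-1 Hz sway spectra.
#' @param duration_s Trial length (s); default 30, the span analysed per trial.
#' @param fs Output sampling rate (Hz); default 512.
#' @param seed Integer RNG seed; simulations are deterministic given the seed.
#' @param theta0 Initial lean angle (rad); default 0.
#' @return An object of class `ip_sim_config`.
#' @export
ip_sim_config <- function(anthro = anthro_model(70, 0.9), kp = NULL, kd = NULL,
                          noise_sd = 0.4, noise_cutoff_hz = 2,
                          duration_s = 30, fs = 512, seed = 1, theta0 = 0) {
  stopifnot(inherits(anthro, "anthro_model"))
  mgh <- anthro$m * anthro$g * anthro$h
  if (is.null(kp)) kp <- 1.2 * mgh
  if (is.null(kd)) kd <- 2 * 0.3 * sqrt(abs(kp - mgh) * anthro$I_a)
  if (kp <= mgh)
    warning("kp <= m*g*h: configuration is statically unstable; expect a fall")
  if (kd < 0) stop("`kd` must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (fs <= 0 || duration_s <= 0) stop("`fs` and `duration_s` must be positive")
  if (noise_cutoff_hz <= 0 || noise_cutoff_hz >= fs)
    stop("`noise_cutoff_hz` must be in (0, fs)")
  structure(list(anthro = anthro, kp = kp, kd = kd, noise_sd = noise_sd,
                 noise_cutoff_hz = noise_cutoff_hz, duration_s = duration_s,
                 fs = fs, seed = as.integer(seed), theta0 = theta0),
            class = "ip_sim_config")
}

#' Simulate single-link quiet stance
#'
#' Integrates the configured pendulum with fixed-step 4th-order Runge-Kutta at
#' the output rate and emits force-plate observables plus ground truth:
#' COP `p_x = tau / (m g)` (small-angle plate equation, feet massless, plate
#' origin at the ankle), COM `x = h * theta`, and `grf_x = m * x..`. A
#' trajectory whose lean exceeds 0.5 rad aborts with a fall condition (error
#' class `ipvi_fall`).
#'
#' @param config An [ip_sim_config()].
#' @return An object of class `simulated_stance`: list with `series`
#'   (a [sway_series()]; COP in mm, GRF in N), `truth_com_x` (mm),
#'   `truth_joint_angles` (one-column matrix, rad) and `config`.
#' @examples
#' sim <- simulate_ip(ip_sim_config(seed = 7, duration_s = 5))
#' cor(sim$truth_com_x - sim$series$cop_x, sim$series$grf_x)
#' @export
simulate_ip <- function(config) {
  stopifnot(inherits(config, "ip_sim_config"))
  a <- config$anthro
  mgh <- a$m * a$g * a$h
  n <- round(config$duration_s * config$fs) + 1L
  eta <- with_seed(config$seed,
                   filtered_torque_noise(2L * n - 1L, 2 * config$fs,
                                         config$noise_sd, config$noise_cutoff_hz))
  A <- matrix(c(0, (mgh - config$kp) / a$I_a,
                1, -config$kd / a$I_a), 2, 2)
  s_dir <- c(0, 1 / a$I_a)  # noise torque applied at the ankle
  Z <- propagate_lti(A, s_dir, eta, 1 / config$fs, z0 = c(config$theta0, 0), n)
  theta <- Z[1, ]; dtheta <- Z[2, ]
  if (max(abs(theta)) > 0.5)
    stop(errorCondition("simulated stance fell: |theta| exceeded 0.5 rad",
                        class = c("ipvi_fall", "error", "condition")))
  eta_full <- eta[seq(1L, 2L * n - 1L, by = 2L)]
  tau <- config$kp * theta + config$kd * dtheta - eta_full
  ddtheta <- ((mgh - config$kp) * theta - config$kd * dtheta + eta_full) / a$I_a
  series <- sway_series(fs = config$fs, t0 = 0,
                        cop_x = 1000 * tau / (a$m * a$g),
                        grf_x = a$m * a$h * ddtheta)
  structure(list(series = series,
                 truth_com_x = 1000 * a$h * theta,
                 truth_joint_angles = matrix(theta, ncol = 1,
                                             dimnames = list(NULL, "ankle")),
                 config = config),
            class = "simulated_stance")
}

#' Configuration for the two-link (ankle-hip) quiet-stance simulator
#'
#' Linearized sagittal-plane double pendulum in absolute segment angles
#' `(theta1, theta2)` with passive-plus-active joint stiffness and damping and
#' per-joint filtered torque noise. The ankle-hip model is the canonical
#' counterexample to the single-link pendulum: with a compliant hip the upper
#' body moves relative to the legs and the pendulum identity degrades, while
#' in the stiff-hip limit the model converges to the single-link pendulum with
#' the composite segment's mass, COM height and inertia (see
#' [composite_anthro()]).
#'
#' Segment defaults approximate a 70 kg adult: lower segment (both legs minus
#' feet) 22.4 kg, ankle-to-hip length 0.85 m, COM 0.45 m above the ankle;
#' upper segment (head-arms-trunk) 47.6 kg, COM 0.32 m above the hip. Own-COM
#' inertias use the slender-rod value `m L^2 / 12`.
#'
#' Linear stability of the full state matrix (eigenvalue real parts < 0) is
#' checked at construction.
#'
#' @param lower,upper Segment parameter lists: `mass` (kg), `length`
#'   (joint-to-joint, m; for `upper` the segment length only sets the default
#'   inertia), `com_offset` (COM distance above the segment's lower joint, m),
#'   `inertia` (about own COM, kg m^2).
#' @param k_ankle,c_ankle Ankle stiffness (N m/rad) and damping (N m s/rad);
#'   defaults `1.2 * Mtot g h_c` and critical-ratio 0.3 as in [ip_sim_config()].
#' @param k_hip,c_hip Hip stiffness and damping; defaults `10 * k_ankle`, 20.
#' @param ankle_noise_sd,hip_noise_sd Filtered torque-noise SDs (N m);
#'   defaults 0.4 and `0.5 * ankle_noise_sd`.
#' @param noise_cutoff_hz,duration_s,fs,seed As in [ip_sim_config()].
#' @param theta0 Initial absolute segment angles (rad), length 2.
#' @return An object of class `double_link_config`.
#' @export
double_link_config <- function(lower = list(mass = 22.4, length = 0.85,
                                            com_offset = 0.45),
                               upper = list(mass = 47.6, length = 0.75,
                                            com_offset = 0.32),
                               k_ankle = NULL, c_ankle = NULL,
                               k_hip = NULL, c_hip = 20,
                               ankle_noise_sd = 0.4, hip_noise_sd = NULL,
                               noise_cutoff_hz = 2, duration_s = 30, fs = 512,
                               seed = 1, theta0 = c(0, 0), g = 9.81) {
  fill_inertia <- function(seg) {
    if (is.null(seg$inertia)) seg$inertia <- seg$mass * seg$length^2 / 12
    seg
  }
  lower <- fill_inertia(lower); upper <- fill_inertia(upper)
  if (any(unlist(lower[c("mass", "length", "com_offset", "inertia")]) <= 0) ||
      any(unlist(upper[c("mass", "length", "com_offset", "inertia")]) <= 0))
    stop("all segment masses, lengths, offsets and inertias must be positive")
  g1 <- (lower$mass * lower$com_offset + upper$mass * lower$length) * g
  g2 <- upper$mass * upper$com_offset * g
  if (is.null(k_ankle)) k_ankle <- 1.2 * (g1 + g2)
  if (is.null(k_hip)) k_hip <- 10 * k_ankle
  if (is.null(hip_noise_sd)) hip_noise_sd <- 0.5 * ankle_noise_sd
  Mtot <- lower$mass + upper$mass
  h_c <- (g1 + g2) / (Mtot * g)
  if (is.null(c_ankle))
    c_ankle <- 2 * 0.3 * sqrt(abs(k_ankle - Mtot * g * h_c) *
                                composite_inertia(lower, upper))
  cfg <- structure(list(lower = lower, upper = upper,
                        k_ankle = k_ankle, c_ankle = c_ankle,
                        k_hip = k_hip, c_hip = c_hip,
                        ankle_noise_sd = ankle_noise_sd,
                        hip_noise_sd = hip_noise_sd,
                        noise_cutoff_hz = noise_cutoff_hz,
                        duration_s = duration_s, fs = fs,
                        seed = as.integer(seed), theta0 = theta0, g = g),
                   class = "double_link_config")
  ev <- eigen(double_link_state_matrix(cfg), only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop("double-link configuration is linearly unstable ",
         "(a state-matrix eigenvalue has non-negative real part)")
  cfg
}

composite_inertia <- function(lower, upper) {
  lower$inertia + lower$mass * lower$com_offset^2 +
    upper$inertia + upper$mass * (lower$length + upper$com_offset)^2
}

#' Composite single-link equivalent of a two-link configuration
#'
#' When the hip is rigid the two-link body is mechanically a single pendulum
#' with total mass, mass-weighted COM height and parallel-axis inertia about
#' the ankle. Useful for pairing two-link runs with their single-link limit.
#'
#' @param cfg A [double_link_config()].
#' @return An [anthro_model()].
#' @export
composite_anthro <- function(cfg) {
  stopifnot(inherits(cfg, "double_link_config"))
  Mtot <- cfg$lower$mass + cfg$upper$mass
  h_c <- (cfg$lower$mass * cfg$lower$com_offset +
            cfg$upper$mass * (cfg$lower$length + cfg$upper$com_offset)) / Mtot
  anthro_model(Mtot, h_c, composite_inertia(cfg$lower, cfg$upper), g = cfg$g)
}

# Mass, gravity, stiffness and damping matrices of the linearized two-link
# model in absolute angles; state z = (theta1, theta2, dtheta1, dtheta2).
double_link_matrices <- function(cfg) {
  m1 <- cfg$lower$mass; m2 <- cfg$upper$mass
  L1 <- cfg$lower$length; d1 <- cfg$lower$com_offset; d2 <- cfg$upper$com_offset
  M <- matrix(c(cfg$lower$inertia + m1 * d1^2 + m2 * L1^2, m2 * L1 * d2,
                m2 * L1 * d2, cfg$upper$inertia + m2 * d2^2), 2, 2)
  G <- diag(c((m1 * d1 + m2 * L1) * cfg$g, m2 * d2 * cfg$g))
  K <- matrix(c(cfg$k_ankle + cfg$k_hip, -cfg$k_hip,
                -cfg$k_hip, cfg$k_hip), 2, 2)
  C <- matrix(c(cfg$c_ankle + cfg$c_hip, -cfg$c_hip,
                -cfg$c_hip, cfg$c_hip), 2, 2)
  # noise torques: ankle actuator on link 1; hip actuator between the links
  S <- matrix(c(1, 0, -1, 1), 2, 2)
  list(M = M, G = G, K = K, C = C, S = S)
}

double_link_state_matrix <- function(cfg) {
  mm <- double_link_matrices(cfg)
  Minv <- solve(mm$M)
  rbind(cbind(matrix(0, 2, 2), diag(2)),
        cbind(Minv %*% (mm$G - mm$K), -Minv %*% mm$C))
}

#' Simulate two-link (ankle-hip) quiet stance
#'
#' Integrates the linearized ankle-hip double pendulum with fixed-step RK4 at
#' the output rate. COP comes from the transmitted ankle torque via the
#' small-angle plate equation; `grf_x` is total mass times the AP acceleration
#' of the combined COM; `truth_com_x` is the mass-weighted segment COM.
#'
#' With `hip_locked = TRUE` the hip joint is constrained rigid
#' (`theta2 = theta1`) and the dynamics collapse, through the same two-link
#' matrices, to the composite single pendulum — a mechanical-equivalence
#' oracle against [simulate_ip()] with [composite_anthro()] parameters.
#'
#' @param config A [double_link_config()].
#' @param hip_locked Logical; rigidly attach the upper segment.
#' @return A `simulated_stance` (see [simulate_ip()]) whose
#'   `truth_joint_angles` has columns `ankle` and `hip` (absolute segment
#'   angles, rad).
#' @export
simulate_double_link <- function(config, hip_locked = FALSE) {
  stopifnot(inherits(config, "double_link_config"))
  mm <- double_link_matrices(config)
  Mtot <- config$lower$mass + config$upper$mass
  n <- round(config$duration_s * config$fs) + 1L
  noises <- with_seed(config$seed, list(
    ankle = filtered_torque_noise(2L * n - 1L, 2 * config$fs,
                                  config$ankle_noise_sd, config$noise_cutoff_hz),
    hip = filtered_torque_noise(2L * n - 1L, 2 * config$fs,
                                config$hip_noise_sd, config$noise_cutoff_hz)))
  g_vec <- diag(mm$G)   # (g1, g2); note g1 + g2 = Mtot g h_c

  if (hip_locked) {
    ones <- c(1, 1)
    I_c <- drop(ones %*% mm$M %*% ones)
    A <- matrix(c(0, (sum(g_vec) - config$k_ankle) / I_c,
                  1, -config$c_ankle / I_c), 2, 2)
    s_dir <- c(0, 1 / I_c)  # hip noise is internal to the rigid body
    Z <- propagate_lti(A, s_dir, noises$ankle, 1 / config$fs,
                       z0 = c(config$theta0[1], 0), n)
    theta <- rbind(Z[1, ], Z[1, ])
    dtheta <- rbind(Z[2, ], Z[2, ])
    eta_a <- noises$ankle[seq(1L, 2L * n - 1L, by = 2L)]
    ddtheta1 <- ((sum(g_vec) - config$k_ankle) * theta[1, ] -
                   config$c_ankle * dtheta[1, ] + eta_a) / I_c
    ddtheta <- rbind(ddtheta1, ddtheta1)
  } else {
    Minv <- solve(mm$M)
    A <- double_link_state_matrix(config)
    Sf <- rbind(matrix(0, 2, 2), Minv %*% mm$S)
    eta2 <- rbind(noises$ankle, noises$hip)
    Z <- propagate_lti(A, Sf, eta2, 1 / config$fs,
                       z0 = c(config$theta0, 0, 0), n)
    theta <- Z[1:2, , drop = FALSE]
    dtheta <- Z[3:4, , drop = FALSE]
    full_idx <- seq(1L, 2L * n - 1L, by = 2L)
    eta_full <- rbind(noises$ankle[full_idx], noises$hip[full_idx])
    rhs <- (mm$G - mm$K) %*% theta - mm$C %*% dtheta + mm$S %*% eta_full
    ddtheta <- Minv %*% rhs
  }
  if (max(abs(theta)) > 0.5)
    stop(errorCondition("simulated stance fell: |theta| exceeded 0.5 rad",
                        class = c("ipvi_fall", "error", "condition")))

  # transmitted ankle torque (restoring + noise actuator at the ankle)
  eta_a <- noises$ankle[seq(1L, 2L * n - 1L, by = 2L)]
  tau_a <- config$k_ankle * theta[1, ] + config$c_ankle * dtheta[1, ] - eta_a
  com_m <- drop(g_vec %*% theta) / (Mtot * config$g)
  ddcom_m <- drop(g_vec %*% ddtheta) / (Mtot * config$g)
  series <- sway_series(fs = config$fs, t0 = 0,
                        cop_x = 1000 * tau_a / (Mtot * config$g),
                        grf_x = Mtot * ddcom_m)
  structure(list(series = series,
                 truth_com_x = 1000 * com_m,
                 truth_joint_angles = matrix(t(theta), ncol = 2,
                                             dimnames = list(NULL, c("ankle", "hip"))),
                 config = config),
            class = "simulated_stance")
}

#' @export
print.simulated_stance <- function(x, ...) {
  cat(sprintf("<simulated_stance> %s, %g s @ %g Hz, COM range %.2f mm\n",
              if (ncol(x$truth_joint_angles) == 1) "single-link" else "two-link",
              sway_duration(x$series), x$series$fs,
              diff(range(x$truth_com_x))))
  invisible(x)
}

# --- internal numerics ------------------------------------------------------

# Exact discretization of the LTI system z' = A z + S eta(t): the state part
# is propagated with the matrix exponential and the forcing, taken piecewise
# linear between nodes of the half-step grid (2 fs), contributes through the
# Van Loan blocks P = int_0^h2 e^{A(h2-s)} ds and Q = int_0^h2 e^{A(h2-s)} s ds
# obtained from one augmented matrix exponential. Unconditionally stable, so
# arbitrarily stiff joint stiffnesses integrate correctly at the output rate,
# and the noise stream consumed is identical across stiffness settings
# (paired-seed comparisons stay paired).
# eta: vector (one channel) or matrix (channels x (2n-1)); S conformable.
propagate_lti <- function(A, S, eta, h, z0, n) {
  d <- length(z0)
  h2 <- h / 2
  N <- rbind(cbind(A, diag(d), matrix(0, d, d)),
             matrix(0, 2L * d, 3L * d))
  N[(d + 1L):(2L * d), (2L * d + 1L):(3L * d)] <- diag(d)
  E <- as.matrix(Matrix::expm(N * h2))
  Ad <- E[1:d, 1:d, drop = FALSE]
  P <- E[1:d, (d + 1L):(2L * d), drop = FALSE]
  Q <- E[1:d, (2L * d + 1L):(3L * d), drop = FALSE]
  B0 <- P - Q / h2
  B1 <- Q / h2
  if (is.null(dim(eta))) eta <- matrix(eta, nrow = 1)
  S <- matrix(S, nrow = d)
  # compose the two half-steps of each output step into one affine update
  R <- Ad %*% Ad
  k0 <- seq(1L, 2L * n - 3L, by = 2L)
  U <- ((Ad %*% B0) %*% S) %*% eta[, k0, drop = FALSE] +
       (((Ad %*% B1 + B0)) %*% S) %*% eta[, k0 + 1L, drop = FALSE] +
       (B1 %*% S) %*% eta[, k0 + 2L, drop = FALSE]
  Z <- matrix(0, d, n)
  z <- z0
  Z[, 1L] <- z
  for (k in seq_len(n - 1L)) {
    z <- R %*% z + U[, k]
    Z[, k + 1L] <- z
  }
  Z
}

# White Gaussian noise shaped by a 2nd-order Butterworth low-pass, scaled so
# the stationary SD of the output equals `sd`. The scale uses the filter's
# white-noise gain sqrt(sum h[k]^2) computed from its impulse response, so it
# does not depend on the realization.
filtered_torque_noise <- function(n, fs, sd, cutoff_hz) {
  w <- stats::rnorm(n)
  if (sd == 0) return(numeric(n))
  ba <- signal::butter(2, 2 * cutoff_hz / fs, type = "low")
  L <- max(1024L, ceiling(6 * fs / cutoff_hz))
  h_imp <- as.numeric(signal::filter(ba, c(1, numeric(L - 1L))))
  gain <- sqrt(sum(h_imp^2))
  as.numeric(signal::filter(ba, w)) * (sd / gain)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
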
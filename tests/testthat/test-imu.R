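test_that("static input gives identity decomposition", {
  kin <- static_kin()
  o <- estimate_orientation(kin)
  expect_equal(o$gravity_head[100, ], c(0, 0, 1), tolerance = 1e-9)
  expect_lt(max(abs(o$nongrav_head)), 1e-9)
  # with accelerometer noise the residual stays at the noise scale
  set.seed(5)
  kin2 <- static_kin(acc_noise = 0.01)
  o2 <- estimate_orientation(kin2)
  expect_lt(sqrt(mean(o2$nongrav_head^2)), 0.02)
})

test_that("90-degree roll is tracked within a degree (noiseless)", {
  fs <- 250; n <- 2 * fs
  om <- matrix(0, n, 3); om[, 1] <- 45
  q_true <- integrate_gyro(om, 1 / fs)
  acc <- quat_rotate(q_true, matrix(c(0, 0, 1), n, 3, byrow = TRUE),
                     inverse = TRUE)
  kin <- kinematic_series((seq_len(n) - 1) / fs, om, acc)
  o <- estimate_orientation(kin)
  ang <- acos(min(1, sum(o$gravity_head[n, ] * c(0, 1, 0)))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("filter gain endpoints behave as documented", {
  s <- short_session(seed = 11, duration = 20)
  # gain 0: pure gyro integration
  o0 <- estimate_orientation(s$kin, correction_gain = 0,
                             q0 = c(1, 0, 0, 0))
  qg <- integrate_gyro(s$kin$omega, 1 / s$kin$sample_rate)
  expect_equal(o0$q, qg, tolerance = 1e-9)
  # gain 1: estimated gravity equals the normalized accelerometer vector
  o1 <- estimate_orientation(s$kin, correction_gain = 1)
  an <- s$kin$acc / sqrt(rowSums(s$kin$acc^2))
  expect_equal(o1$gravity_head, an, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(estimate_orientation(s$kin, correction_gain = 2),
               "correction_gain")
})

test_that("gravity error shrinks as gyro noise shrinks (noiseless limit)", {
  errs <- vapply(c(2, 0.5, 0), function(gn) {
    sim <- simulate_head_kinematics(
      simulation_config(duration = 60, seed = 13, gyro_noise_sd = gn,
                        accel_noise_sd = 0))
    o <- estimate_orientation(sim$kin)
    median(acos(pmin(1, rowSums(o$gravity_head *
                                  sim$truth$gravity_head))) * 180 / pi)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("decomposition is exact and pitch couples a_x^G with a_z^G", {
  s <- short_session(seed = 11, duration = 20)
  dec <- decompose_acceleration(s$kin, s$orient)
  expect_lt(max(abs(s$kin$acc - (dec$ag + dec$ang))), 1e-12)
  expect_lt(max(abs(sqrt(rowSums(dec$ag^2)) - 1)), 1e-9)
  # pure pitch oscillation, noiseless: a_x^G and a_z^G co-vary positively
  fs <- 250; n <- 8 * fs; t <- (seq_len(n) - 1) / fs
  om <- cbind(0, -40 * sin(2 * pi * 0.5 * t), 0) # nose-up/down wobble
  qt <- integrate_gyro(om, 1 / fs)
  acc <- quat_rotate(qt, matrix(c(0, 0, 1), n, 3, byrow = TRUE), TRUE)
  kin <- kinematic_series(t, om, acc)
  o <- estimate_orientation(kin)
  expect_gt(cor(o$gravity_head[, 1], 1 - o$gravity_head[, 3]), 0.9)
})

test_that("rotate_to_earth_frame matches single-rotation algebra and preserves norms", {
  # head rolled 90 deg right (+x roll): head-frame yaw becomes earth -y
  q <- quat_from_axis_angle(c(1, 0, 0), pi / 2)
  n <- 10
  orient <- orientation_series(matrix(q, n, 4, byrow = TRUE),
                               matrix(c(0, 1, 0), n, 3, byrow = TRUE),
                               matrix(0, n, 3), seq_len(n))
  v <- matrix(c(0, 0, 100), n, 3, byrow = TRUE)
  ve <- rotate_to_earth_frame(v, orient)
  expect_equal(ve[1, ], c(0, -100, 0), tolerance = 1e-9)
  s <- short_session(seed = 11, duration = 20)
  we <- rotate_to_earth_frame(s$kin$omega, s$orient)
  expect_lt(max(abs(sqrt(rowSums(we^2)) - sqrt(rowSums(s$kin$omega^2)))),
            1e-9)
  # identity orientation: output equals input
  oid <- orientation_series(matrix(c(1, 0, 0, 0), n, 4, byrow = TRUE),
                            matrix(c(0, 0, 1), n, 3, byrow = TRUE),
                            matrix(0, n, 3), seq_len(n))
  expect_equal(rotate_to_earth_frame(v, oid), v, ignore_attr = TRUE)
})

test_that("earth-frame omega_z of an earth-vertical spin ignores tilt wobble", {
  # compose: constant earth-vertical spin + pitch wobble, built in the
  # generator's own convention by integrating the head-frame rate of the
  # composed motion
  fs <- 250; n <- 20 * fs; t <- (seq_len(n) - 1) / fs
  spin <- 60 # deg/s about earth z
  qs <- matrix(0, n, 4); qs[1, ] <- c(1, 0, 0, 0)
  wob <- -30 * sin(2 * pi * 0.4 * t) # head-frame pitch rate
  om <- matrix(0, n, 3)
  for (i in 2:n) {
    # head-frame rate = wobble (body) + spin axis expressed in head frame
    zb <- quat_rotate(qs[i - 1, ], c(0, 0, 1), inverse = TRUE)
    om[i - 1, ] <- c(0, wob[i - 1], 0) + spin * zb
    dq <- quat_from_axis_angle(om[i - 1, ],
                               sqrt(sum(om[i - 1, ]^2)) * pi / 180 / fs)
    if (sum(om[i - 1, ]^2) == 0) dq <- c(1, 0, 0, 0)
    qs[i, ] <- quat_normalize(quat_multiply(qs[i - 1, ], dq))
  }
  om[n, ] <- om[n - 1, ]
  g <- quat_rotate(qs, matrix(c(0, 0, 1), n, 3, byrow = TRUE), TRUE)
  orient <- orientation_series(qs, g, matrix(0, n, 3), t)
  we <- rotate_to_earth_frame(om, orient)
  expect_lt(max(abs(we[, 3] - spin)), 1.5) # constant despite the wobble
})

test_that("band power fractions behave on canonical signals", {
  fs <- 250; t <- seq(0, 20, by = 1 / fs)
  bands <- list(c(0, 2), c(2, 20))
  sine <- sin(2 * pi * 5 * t)
  bf <- band_power_fractions(sine, bands, fs)
  expect_gt(bf$band_fraction[2, 1], 0.99)
  set.seed(3)
  wn <- rnorm(length(t))
  bfw <- band_power_fractions(wn, list(c(0, 25), c(25, 50), c(50, 100)),
                              fs)
  expect_equal(bfw$band_fraction[2, 1] / bfw$band_fraction[1, 1], 1,
               tolerance = 0.1)
  expect_equal(bfw$band_fraction[3, 1] / (2 * bfw$band_fraction[1, 1]), 1,
               tolerance = 0.1)
  dc <- rep(3, length(t))
  bfd <- band_power_fractions(dc, bands, fs)
  expect_gt(bfd$band_fraction[1, 1], 0.999)
  expect_error(band_power_fractions(sine, list(c(150, 200)), fs),
               "Nyquist")
  expect_error(band_power_fractions(sine[1:100], bands, fs), "2 s")
})

test_that("lever-arm cross-correlation structure matches the generator's", {
  sim <- simulate_head_kinematics(
    simulation_config(duration = 60, seed = 14, accel_noise_sd = 0,
                      gyro_noise_sd = 0))
  o <- estimate_orientation(sim$kin)
  ra <- rotation_induced_accelerations(sim$truth$omega,
                                       sim$truth$config$lever_arm, 250)
  pred <- ra$tangential
  # the measured non-gravitational acceleration correlates with the
  # predicted tangential acceleration channel by channel
  cors <- vapply(1:3, function(j) cor(o$nongrav_head[, j], pred[, j]),
                 numeric(1))
  expect_true(all(cors > 0.5))
})

test_that("kinematic derivatives recover analytic derivatives", {
  fs <- 250; t <- seq(0, 10, by = 1 / fs); n <- length(t)
  k <- 3.7
  kin <- kinematic_series(t, cbind(0, 0, k * t),
                          matrix(c(0, 0, 1), n, 3, byrow = TRUE))
  o <- estimate_orientation(static_kin(10 + 1 / fs))
  d <- kinematic_derivatives(kin, o)
  expect_equal(max(abs(d$omega_dot[, 3] - k)), 0, tolerance = 1e-6)
  expect_lt(max(abs(d$gravity_jerk)), 1e-9) # constant a^G
  f <- 2; A <- 30
  kin2 <- kinematic_series(t, cbind(A * sin(2 * pi * f * t), 0, 0),
                           matrix(c(0, 0, 1), n, 3, byrow = TRUE))
  d2 <- kinematic_derivatives(kin2, o)
  interior <- 100:(n - 100)
  expect_equal(max(abs(d2$omega_dot[interior, 1])), 2 * pi * f * A,
               tolerance = 0.01)
  expect_error(kinematic_derivatives(
    kinematic_series(t[1:2], matrix(0, 2, 3),
                     matrix(c(0, 0, 1), 2, 3, byrow = TRUE)), o),
    "too short")
})
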
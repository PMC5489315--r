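test_that("OLS sensitivity fit matches the normal-equation oracle exactly", {
  s <- short_session(seed = 51, duration = 20)
  set.seed(511)
  fr <- 30 + 0.1 * s$kin$omega[, 1] - 0.25 * s$kin$omega[, 3] +
    rnorm(length(s$kin$t), sd = 5)
  sv <- fit_sensitivity_at_lag(fr, s$kin$omega, 0, 250)
  X <- cbind(1, s$kin$omega)
  beta <- solve(t(X) %*% X, t(X) %*% fr)
  expect_equal(sv$intercept, beta[1], tolerance = 1e-8)
  expect_equal(sv$components, beta[-1], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sv$gain, sqrt(sum(beta[-1]^2)), tolerance = 1e-8)
})

test_that("noiseless linear unit is recovered exactly at its lag", {
  s <- short_session(seed = 51, duration = 20)
  n <- length(s$kin$t)
  off <- 10 # 40 ms at 250 Hz
  fr <- numeric(n)
  fr[(off + 1):n] <- 40 + 0.2 * s$kin$omega[1:(n - off), 3]
  sv <- fit_sensitivity_at_lag(fr[1:n], s$kin$omega, 0.04, 250)
  expect_equal(sv$components, c(0, 0, 0.2), tolerance = 1e-6)
  expect_equal(sv$intercept, 40, tolerance = 1e-4)
})

test_that("rank-deficient designs are flagged, not silently fitted", {
  fr <- rnorm(2000)
  om <- matrix(0, 2000, 3)
  expect_warning(sv <- fit_sensitivity_at_lag(fr, om, 0, 250),
                 "rank-deficient")
  expect_true(all(is.na(sv$components)))
  expect_false(sv$ok)
})

test_that("gain is invariant to rate offsets and equivariant under rotation", {
  s <- short_session(seed = 52, duration = 30)
  set.seed(521)
  fr <- 30 + 0.15 * s$kin$omega[, 2] + rnorm(length(s$kin$t), sd = 3)
  g1 <- fit_sensitivity_at_lag(fr, s$kin$omega, 0, 250)
  g2 <- fit_sensitivity_at_lag(fr + 17, s$kin$omega, 0, 250)
  expect_equal(g1$gain, g2$gain, tolerance = 1e-10)
  expect_equal(g1$components, g2$components, tolerance = 1e-10)
  R <- rotmat_from_quat(quat_from_axis_angle(c(1, 2, 3), 0.8))
  g3 <- fit_sensitivity_at_lag(fr, s$kin$omega %*% t(R), 0, 250)
  expect_equal(g3$gain, g1$gain, tolerance = 1e-8)
  expect_equal(drop(R %*% g1$components), g3$components, tolerance = 1e-8)
})

test_that("gain-lag curve finds the planted lag and shuffle band excludes it", {
  s <- short_session(seed = 53, duration = 240)
  spec <- tuning_spec("rotation_head_frame", baseline_rate = 50,
                      gain = 0.3, preferred_axis = c(0, 1, 0),
                      response_lag = 0.04, isi_cv = 0.6)
  ua <- unit_activity(simulate_unit(s$kin, s$truth, spec, seed = 531),
                      s$kin)
  glc <- gain_lag_curve(ua$fr_instant, s$kin$omega, 250,
                        lag_grid = seq(-0.2, 0.2, by = 0.02),
                        n_shuffles = 100, seed = 53)
  expect_equal(glc$optimal_lag, 0.04, tolerance = 0.021)
  expect_true(glc$significant)
  # the noiseless-rate oracle curve is strictly unimodal around the lag
  rate <- tuning_rate(spec, s$truth)
  glc_nl <- gain_lag_curve(rate, s$kin$omega, 250,
                           lag_grid = seq(-0.2, 0.2, by = 0.02),
                           n_shuffles = 0)
  # unique peak at the planted lag, locally unimodal (side lobes further
  # out reflect the oscillatory autocorrelation of omega itself)
  pk <- which.max(glc_nl$gains)
  expect_equal(glc_nl$lags[pk], 0.04, tolerance = 1e-9)
  expect_true(all(diff(glc_nl$gains[(pk - 3):pk]) > 0))
  expect_true(all(diff(glc_nl$gains[pk:(pk + 3)]) < 0))
  expect_lt(max(glc_nl$gains[-pk]), glc_nl$gains[pk])
  # untuned unit: whole curve inside the shuffle band
  set.seed(532)
  spk <- spikes_from_rate(rep(40, length(s$kin$t)), s$kin$t, 0.95)
  un <- unit_activity(spk, s$kin)
  glc0 <- gain_lag_curve(un$fr_instant, s$kin$omega, 250,
                         lag_grid = seq(-0.2, 0.2, by = 0.02),
                         n_shuffles = 100, seed = 54)
  expect_false(glc0$significant)
  expect_true(all(glc0$gains < glc0$shuffle_mean + 3 * glc0$shuffle_sd))
  expect_error(gain_lag_curve(ua$fr_instant, s$kin$omega, 250,
                              lag_grid = c(-2, 0, 2)), "1 s")
})

test_that("receptive fields expose gated and reversing rotational tuning", {
  s <- short_session(seed = 55, duration = 240)
  lag_grid <- seq(-0.2, 0.2, by = 0.04)
  gated <- tuning_spec("gated_mixed", baseline_rate = 40, gain = 0.3,
                       preferred_axis = c(0, 0, 1), response_lag = 0,
                       isi_cv = 0.5,
                       gate = list(axis = "x", sign = 1, threshold = 0,
                                   mode = "on_off"))
  ua <- unit_activity(simulate_unit(s$kin, s$truth, gated, seed = 551),
                      s$kin)
  gx <- s$orient$gravity_head[, 1]
  rf_up <- inertio_temporal_rf(ua$fr_instant, s$kin$omega[, 3], 250,
                               lag_grid = lag_grid, condition = gx > 0.1)
  rf_dn <- inertio_temporal_rf(ua$fr_instant, s$kin$omega[, 3], 250,
                               lag_grid = lag_grid, condition = gx < -0.1)
  l0 <- which.min(abs(lag_grid))
  expect_gt(rf_slopes(rf_up)[l0], 0.15)
  expect_lt(abs(rf_slopes(rf_dn)[l0]), 0.1)
  # sign-reversing unit: slopes of opposite sign per hemifield
  revu <- tuning_spec("gated_mixed", baseline_rate = 40, gain = 0.3,
                      preferred_axis = c(0, 0, 1), response_lag = 0,
                      isi_cv = 0.5,
                      gate = list(axis = "x", sign = 1, threshold = 0,
                                  mode = "reverse"))
  ur <- unit_activity(simulate_unit(s$kin, s$truth, revu, seed = 552),
                      s$kin)
  sup <- rf_slopes(inertio_temporal_rf(ur$fr_instant, s$kin$omega[, 3],
                                       250, lag_grid = lag_grid,
                                       condition = gx > 0.1))[l0]
  sdn <- rf_slopes(inertio_temporal_rf(ur$fr_instant, s$kin$omega[, 3],
                                       250, lag_grid = lag_grid,
                                       condition = gx < -0.1))[l0]
  expect_gt(sup, 0.15)
  expect_lt(sdn, -0.15)
})

test_that("receptive-field cells are convex means and flat for constant rate", {
  s <- short_session(seed = 55, duration = 60)
  fr <- rep(25, length(s$kin$t))
  rf <- inertio_temporal_rf(fr, s$kin$omega[, 3], 250,
                            lag_grid = seq(-0.1, 0.1, by = 0.05))
  vals <- rf$mean_rate[is.finite(rf$mean_rate)]
  expect_true(all(abs(vals - 25) < 1e-9))
  # empty condition: everything masked
  rf0 <- inertio_temporal_rf(fr, s$kin$omega[, 3], 250,
                             condition = rep(FALSE, length(fr)))
  expect_true(all(!is.finite(rf0$mean_rate)))
  # slope at optimal lag matches the fitted component (planted unit)
  spec <- tuning_spec("rotation_head_frame", baseline_rate = 50,
                      gain = 0.3, preferred_axis = c(0, 0, 1),
                      response_lag = 0, isi_cv = 0.5)
  s2 <- short_session(seed = 56, duration = 240)
  ua <- unit_activity(simulate_unit(s2$kin, s2$truth, spec, seed = 561),
                      s2$kin)
  sv <- fit_sensitivity_at_lag(ua$fr_instant, s2$kin$omega, 0, 250)
  rf2 <- inertio_temporal_rf(ua$fr_instant, s2$kin$omega[, 3], 250,
                             lag_grid = 0)
  expect_equal(rf_slopes(rf2)[1], sv$components[3], tolerance = 0.1,
               ignore_attr = TRUE)
})
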
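test_that("estimate is a convex combination of observed rates", {
  s <- short_session(seed = 41, duration = 30)
  set.seed(411)
  spk <- spikes_from_rate(rep(40, length(s$kin$t)), s$kin$t, 0.95)
  ua <- unit_activity(spk, s$kin)
  est <- estimate_rate(ua, s$channels, s$kin$t, parameter_space("omega"))
  ok <- is.finite(est$rho)
  expect_true(all(est$rho[ok] >= min(ua$fr_instant)))
  expect_true(all(est$rho[ok] <= max(ua$fr_instant)))
  expect_gte(min(est$rho[ok]), 0)
})

test_that("deterministic rotation-driven rate is predicted with r2 > 0.9", {
  s <- short_session(seed = 41, duration = 120)
  fr <- 40 + 0.2 * s$truth$omega[, 3]
  est <- estimate_rate(list(fr_instant = fr), s$channels, s$kin$t,
                       parameter_space("omega"))
  expect_gt(est$r2, 0.9)
  expect_gt(est$coverage, 0.5)
})

test_that("constant rate gives rho equal to it and r2 near zero", {
  s <- short_session(seed = 41, duration = 30)
  fr <- rep(40, length(s$kin$t))
  est <- estimate_rate(list(fr_instant = fr), s$channels, s$kin$t,
                       parameter_space("omega"))
  ok <- is.finite(est$rho)
  expect_true(all(abs(est$rho[ok] - 40) < 1e-9))
  expect_true(is.na(est$r2) || est$r2 < 0.01) # zero-variance estimate
})

test_that("tiny radius drives coverage to zero without crashing", {
  s <- short_session(seed = 41, duration = 30)
  fr <- rep(40, length(s$kin$t))
  expect_warning(
    est <- estimate_rate(list(fr_instant = fr), s$channels, s$kin$t,
                         parameter_space("omega", d = 1e-8)),
    "zero coverage")
  expect_equal(est$coverage, 0)
})

test_that("temporal exclusion blocks trivial self-prediction", {
  s <- short_session(seed = 42, duration = 60)
  set.seed(421)
  spk <- spikes_from_rate(rep(30, length(s$kin$t)), s$kin$t, 1) # untuned
  ua <- unit_activity(spk, s$kin)
  est_w0 <- estimate_rate(ua, s$channels, s$kin$t,
                          parameter_space("omega", d = 0.05, w = 0,
                                          min_neighbors = 2))
  est_w1 <- estimate_rate(ua, s$channels, s$kin$t,
                          parameter_space("omega", d = 0.05, w = 1,
                                          min_neighbors = 2))
  expect_gt(est_w0$r2, est_w1$r2)
  expect_lt(est_w1$r2, 0.05)
})

test_that("predictability table discriminates planted tuning", {
  s <- short_session(seed = 43, duration = 120)
  spec <- tuning_spec("rotation_head_frame", baseline_rate = 50,
                      gain = 0.4, preferred_axis = c(0, 0, 1),
                      response_lag = 0.04, isi_cv = 0.5)
  ua <- unit_activity(simulate_unit(s$kin, s$truth, spec, seed = 431),
                      s$kin)
  pt <- predictability_table(ua, s$channels, s$kin$t,
                             parameter_space("omega",
                                             lag_grid = seq(-0.1, 0.1,
                                                            by = 0.02)),
                             sets = list(omega = "omega", ag = "ag"),
                             query_stride = 2L)
  expect_gt(pt$r2[pt$set == "omega"], 5 * pt$r2[pt$set == "ag"])
  expect_equal(pt$lag[pt$set == "omega"], 0.04, tolerance = 0.021)
})

test_that("independent estimates correlate for tuned, not untuned, units", {
  s <- short_session(seed = 44, duration = 240)
  fr_det <- 40 + 0.2 * s$truth$omega[, 3] # deterministic, strongly tuned
  r_det <- independent_estimate_correlation(
    list(fr_instant = fr_det), s$channels, s$kin$t,
    parameter_space("omega"), block_length = 30)
  expect_gt(r_det$r, 0.8)
  set.seed(441)
  spk <- spikes_from_rate(rep(40, length(s$kin$t)), s$kin$t, 1)
  ua <- unit_activity(spk, s$kin)
  r_un <- independent_estimate_correlation(ua, s$channels, s$kin$t,
                                           parameter_space("omega"),
                                           block_length = 30)
  expect_lt(abs(r_un$r), 0.15)
  expect_error(independent_estimate_correlation(
    ua, s$channels, s$kin$t, parameter_space("omega"),
    block_length = 100), "4 blocks")
})

test_that("shuffle null is reproducible and centered near zero", {
  s <- short_session(seed = 44, duration = 240)
  spec <- tuning_spec("rotation_head_frame", baseline_rate = 50,
                      gain = 0.4, isi_cv = 0.5, response_lag = 0)
  spk <- simulate_unit(s$kin, s$truth, spec, seed = 442)
  a <- shuffle_null(spk, s$kin, s$channels, parameter_space("omega"),
                    n_iter = 3, seed = 7, query_stride = 4L)
  b <- shuffle_null(spk, s$kin, s$channels, parameter_space("omega"),
                    n_iter = 3, seed = 7, query_stride = 4L)
  expect_identical(a$r_values, b$r_values)
  expect_true(all(abs(a$r_values) <= 1))
  expect_error(shuffle_null(spk, static_kin(15), s$channels,
                            parameter_space("omega")), "twice the minimum")
})

test_that("time-reversed rate series loses its predictability", {
  s <- short_session(seed = 43, duration = 120)
  spec <- tuning_spec("rotation_head_frame", baseline_rate = 50,
                      gain = 0.4, preferred_axis = c(0, 0, 1),
                      response_lag = 0, isi_cv = 0.5)
  ua <- unit_activity(simulate_unit(s$kin, s$truth, spec, seed = 432),
                      s$kin)
  sp <- parameter_space("omega")
  fwd <- estimate_rate(ua, s$channels, s$kin$t, sp)
  rev <- estimate_rate(list(fr_instant = rev(ua$fr_instant)), s$channels,
                       s$kin$t, sp)
  expect_gt(fwd$r2, 0.1)
  expect_lt(rev$r2, 0.02)
})

test_that("cross-recording estimation transfers identical tuning", {
  sa <- short_session(seed = 45, duration = 120)
  sb <- short_session(seed = 46, duration = 120)
  spec <- tuning_spec("rotation_head_frame", baseline_rate = 50,
                      gain = 0.4, preferred_axis = c(0, 0, 1),
                      response_lag = 0, isi_cv = 0.5)
  ua <- unit_activity(simulate_unit(sa$kin, sa$truth, spec, seed = 451),
                      sa$kin)
  ub <- unit_activity(simulate_unit(sb$kin, sb$truth, spec, seed = 452),
                      sb$kin)
  sp <- parameter_space("omega")
  # estimate the rate of recording B from reference recording A
  cross <- estimate_rate(ub, sb$channels, sb$kin$t, sp,
                         reference = list(fr = ua$fr_instant,
                                          params = sa$channels,
                                          t = sa$kin$t),
                         same_recording = FALSE)
  within <- estimate_rate(ub, sb$channels, sb$kin$t, sp)
  expect_gt(cross$r2, 0.5 * within$r2)
  # altered tuning transfers poorly: reference from a unit with the
  # opposite preferred axis
  spec_neg <- tuning_spec("rotation_head_frame", baseline_rate = 50,
                          gain = -0.4, preferred_axis = c(0, 0, 1),
                          response_lag = 0, isi_cv = 0.5)
  ua2 <- unit_activity(simulate_unit(sa$kin, sa$truth, spec_neg,
                                     seed = 453), sa$kin)
  cross2 <- estimate_rate(ub, sb$channels, sb$kin$t, sp,
                          reference = list(fr = ua2$fr_instant,
                                           params = sa$channels,
                                           t = sa$kin$t),
                          same_recording = FALSE)
  ok <- is.finite(cross2$rho)
  r_wrong <- cor(cross2$rho[ok], ub$fr_instant[ok])
  expect_lt(r_wrong, 0) # anticorrelated tuning transfers with flipped sign
})

test_that("selectivity rule rejects non-finite or negative input", {
  expect_error(classify_inertial_selectivity(NA, 0.1))
  expect_error(classify_inertial_selectivity(-0.1, 0.1))
})
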
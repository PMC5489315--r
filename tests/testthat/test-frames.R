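# Reference-frame analyses on a shared 300 s session with three planted
# units: head-frame pitch tuning, earth-vertical-axis tuning, and an equal
# mixture.

frames_fixture <- function() {
  if (exists("frames_fx", .fixture_cache))
    return(get("frames_fx", .fixture_cache))
  s <- short_session(seed = 71, duration = 300)
  grid <- sphere_grid(162, 20)
  mk_field <- function(fr)
    local_sensitivity_field(fr, s$kin$omega, s$deriv$omega_earth,
                            s$orient$gravity_head, grid, lag = 0.04,
                            sample_rate = 250, n_shuffles = 50, seed = 71)
  hf_spec <- tuning_spec("rotation_head_frame", baseline_rate = 50,
                         gain = 0.4, preferred_axis = c(0, 1, 0),
                         response_lag = 0.04, isi_cv = 0.5)
  ef_spec <- tuning_spec("rotation_earth_frame", baseline_rate = 50,
                         gain = 0.4, preferred_axis = c(0, 0, 1),
                         response_lag = 0.04, isi_cv = 0.5)
  hf <- unit_activity(simulate_unit(s$kin, s$truth, hf_spec, seed = 711),
                      s$kin)
  ef <- unit_activity(simulate_unit(s$kin, s$truth, ef_spec, seed = 712),
                      s$kin)
  mixr <- 0.5 * tuning_rate(hf_spec, s$truth) +
    0.5 * tuning_rate(ef_spec, s$truth)
  mx <- unit_activity(spikes_from_rate(mixr, s$kin$t, 0.5, seed = 713),
                      s$kin)
  fx <- list(s = s, grid = grid,
             f_hf = mk_field(hf$fr_instant), f_ef = mk_field(ef$fr_instant),
             f_mx = mk_field(mx$fr_instant))
  assign("frames_fx", fx, .fixture_cache)
  fx
}

test_that("local sensitivity fields recover the planted frame geometry", {
  fx <- frames_fixture()
  # head-frame unit: internal vectors near-parallel across occupied caps
  occ <- which(is.finite(fx$f_hf$gain_internal) & fx$f_hf$sig_internal)
  expect_gt(length(occ), 5)
  v <- fx$f_hf$internal[occ, , drop = FALSE]
  v <- v / sqrt(rowSums(v^2))
  cs <- (v %*% t(v))[upper.tri(diag(length(occ)))]
  expect_gt(mean(cs), 0.9)
  # earth-frame unit: external near-parallel, internal rotates with tilt
  occ2 <- which(is.finite(fx$f_ef$gain_external) & fx$f_ef$sig_external)
  ve <- fx$f_ef$external[occ2, , drop = FALSE]
  ve <- ve / sqrt(rowSums(ve^2))
  cse <- (ve %*% t(ve))[upper.tri(diag(length(occ2)))]
  expect_gt(mean(cse), 0.9)
  vi <- fx$f_ef$internal[occ2, , drop = FALSE]
  vi <- vi / sqrt(rowSums(vi^2))
  csi <- (vi %*% t(vi))[upper.tri(diag(length(occ2)))]
  expect_lt(mean(csi), mean(cse) - 0.1)
})

test_that("untuned unit yields a mostly insignificant field", {
  fx <- frames_fixture()
  s <- fx$s
  set.seed(714)
  spk <- spikes_from_rate(rep(40, length(s$kin$t)), s$kin$t, 0.95)
  ua <- unit_activity(spk, s$kin)
  f0 <- local_sensitivity_field(ua$fr_instant, s$kin$omega,
                                s$deriv$omega_earth,
                                s$orient$gravity_head, fx$grid,
                                lag = 0, n_shuffles = 50, seed = 72)
  nsig <- sum(f0$sig_internal, na.rm = TRUE)
  nocc <- sum(is.finite(f0$gain_internal))
  expect_lt(nsig, 0.3 * nocc)
})

test_that("collinearity profiles match a brute-force all-pairs oracle", {
  fx <- frames_fixture()
  prof <- collinearity_profile(fx$f_ef, "external", phi_bin_width = 10)
  keep <- which(is.finite(fx$f_ef$external[, 1]) &
                  (fx$f_ef$sig_external %in% TRUE))
  pts <- fx$grid$points[keep, , drop = FALSE]
  v <- fx$f_ef$external[keep, , drop = FALSE]
  v <- v / sqrt(rowSums(v^2))
  edges <- seq(0, 180, by = 10)
  sums <- numeric(18); cnts <- integer(18)
  for (i in seq_len(nrow(pts) - 1)) {
    for (j in (i + 1):nrow(pts)) {
      phi <- acos(min(1, max(-1, sum(pts[i, ] * pts[j, ])))) * 180 / pi
      b <- max(1, findInterval(phi, edges, rightmost.closed = TRUE))
      sums[b] <- sums[b] + sum(v[i, ] * v[j, ])
      cnts[b] <- cnts[b] + 1L
    }
  }
  oracle <- ifelse(cnts > 0, sums / pmax(cnts, 1L), NA_real_)
  expect_equal(prof$S, oracle, tolerance = 1e-12)
  expect_identical(prof$n_pairs, cnts)
})

test_that("identical vectors give S = 1 in every occupied bin", {
  fx <- frames_fixture()
  f <- fx$f_hf
  occ <- is.finite(f$gain_internal)
  f$internal[occ, ] <- matrix(c(0, 1, 0), sum(occ), 3, byrow = TRUE)
  f$sig_internal[occ] <- TRUE
  prof <- collinearity_profile(f, "internal")
  expect_true(all(abs(prof$S[is.finite(prof$S)] - 1) < 1e-12))
})

test_that("frame classification recovers planted reference frames", {
  fx <- frames_fixture()
  cls <- function(f) classify_reference_frame(
    collinearity_profile(f, "internal"),
    collinearity_profile(f, "external"))
  ce <- cls(fx$f_ef); chf <- cls(fx$f_hf); cmx <- cls(fx$f_mx)
  expect_identical(ce$label, "external")
  expect_identical(chf$label, "internal")
  expect_identical(cmx$label, "unclassified")
  expect_gt(ce$delta_s, 0.5)
  expect_lt(chf$delta_s, -0.5)
  expect_lte(abs(cmx$delta_s), 0.5)
})

test_that("classification is monotone in Delta S and handles empty bands", {
  mkprof <- function(Svals)
    structure(list(phi_centers = c(85, 95), S = Svals,
                   n_pairs = c(10L, 10L), frame = "internal",
                   phi_bin_width = 10), class = "collinearity_profile")
  base <- mkprof(c(0, 0))
  labs <- vapply(c(-0.9, -0.4, 0.4, 0.9), function(d)
    classify_reference_frame(base, mkprof(c(d, d)))$label, character(1))
  expect_identical(labs, c("internal", "unclassified", "unclassified",
                           "external"))
  empty <- mkprof(c(NA_real_, NA_real_))
  out <- classify_reference_frame(empty, empty)
  expect_identical(out$label, "unclassified")
  expect_identical(out$reason, "decision band empty")
})

test_that("S is invariant to a global rotation of one frame's vectors", {
  fx <- frames_fixture()
  f <- fx$f_ef
  R <- rotmat_from_quat(quat_from_axis_angle(c(1, 0, 2), 0.7))
  f2 <- f
  occ <- is.finite(f$external[, 1])
  f2$external[occ, ] <- f$external[occ, , drop = FALSE] %*% t(R)
  p1 <- collinearity_profile(f, "external")
  p2 <- collinearity_profile(f2, "external")
  expect_equal(p1$S, p2$S, tolerance = 1e-9)
})

test_that("noiseless head-frame unit has Delta S <= 0 in every bin", {
  fx <- frames_fixture()
  s <- fx$s
  fr <- 50 + 0.4 * s$truth$omega[, 2] # noiseless linear pitch unit
  f <- local_sensitivity_field(fr, s$kin$omega, s$deriv$omega_earth,
                               s$orient$gravity_head, fx$grid, lag = 0,
                               n_shuffles = 0)
  pi_ <- collinearity_profile(f, "internal", require_significant = FALSE)
  pe_ <- collinearity_profile(f, "external", require_significant = FALSE)
  ds <- pe_$S - pi_$S
  expect_true(all(ds[is.finite(ds)] <= 1e-6))
  expect_true(all(abs(pi_$S[is.finite(pi_$S)] - 1) < 0.02))
})
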
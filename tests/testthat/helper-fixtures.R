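# Shared fixtures: short synthetic sessions for unit tests, memoised so each
# is generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# short session with orientation estimate and channel matrix attached
short_session <- function(seed = 1, duration = 60) {
  key <- sprintf("s_%d_%d", seed, duration)
  if (!exists(key, .fixture_cache)) {
    sim <- simulate_head_kinematics(
      simulation_config(duration = duration, seed = seed))
    orient <- estimate_orientation(sim$kin)
    assign(key, list(kin = sim$kin, truth = sim$truth, orient = orient,
                     channels = inertial_channels(sim$kin, orient),
                     deriv = kinematic_derivatives(sim$kin, orient)),
           .fixture_cache)
  }
  get(key, .fixture_cache)
}

# static (motionless, upright) kinematics
static_kin <- function(duration = 4, fs = 250, acc_noise = 0) {
  n <- duration * fs
  t <- (seq_len(n) - 1) / fs
  acc <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  if (acc_noise > 0) acc <- acc + matrix(rnorm(3 * n, sd = acc_noise), n, 3)
  kinematic_series(t, matrix(0, n, 3), acc)
}

# independent R-side quaternion rotation matrix (oracle for rotations)
rotmat_from_quat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# brute-force O(n^2) resampling oracle mirroring the estimator's contract:
# per-channel z-scoring from the reference, Euclidean radius d, temporal
# exclusion |dt| <= w, mean FR at lag offset `off` samples
brute_force_rho <- function(fr, params, t, channels, d, w, off = 0L,
                            min_neighbors = 10) {
  x <- params[, channels, drop = FALSE]
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[sdev == 0] <- 1
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdev, "/")
  n <- nrow(z)
  rho <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(z, 2, z[i, ], "-")^2)
    nb <- which(d2 <= d^2 & abs(t - t[i]) > w)
    fj <- nb + off
    fj <- fj[fj >= 1 & fj <= n]
    if (length(fj) >= min_neighbors) rho[i] <- mean(fr[fj])
  }
  rho
}
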
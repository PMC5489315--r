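# Synthetic sessions: head kinematics with known orientation ground truth and
# spike trains from planted tuning models.  The generator is the test bed for
# the whole pipeline -- there is no deposited recording to run against.

#' Configuration of the kinematics generator
#'
#' Defaults emulate the statistics of rat exploratory head movement reported
#' for head-mounted inertial recordings: angular speed 2.5-97.5 percentiles
#' near 18-287 deg/s, multi-peaked rotational spectra up to 20 Hz with pitch
#' and yaw dominating roll, tilt trajectories autocorrelated over seconds,
#' rotation-coupled non-gravitational acceleration from a ~2 cm lever arm
#' between the head's pivot and the sensor, and white sensor noise.
#'
#' @param duration session length, seconds.
#' @param sample_rate sampling rate, Hz.
#' @param tilt_correlation_time correlation time of the slow tilt-driving
#'   angular velocity, seconds.
#' @param rotation_band_edges edges (Hz) of the band-limited noise processes
#'   summed to form the fast rotational component.
#' @param rotation_scale overall angular-velocity scale, deg/s (per-axis SD
#'   of the fast component before burst modulation).
#' @param roll_attenuation multiplier in (0,1] applied to the roll (x) axis.
#' @param lever_arm 3-vector, meters, from the rotation pivot to the sensor.
#' @param accel_noise_sd accelerometer white noise SD, g.
#' @param gyro_noise_sd gyroscope white noise SD, deg/s.
#' @param seed integer RNG seed; identical seeds reproduce output
#'   bit-identically.
#' @param slow_ratio SD of the slow tilt-driving component relative to
#'   `rotation_scale`.
#' @param burst_sd log-SD of the slow lognormal envelope that modulates the
#'   fast component (movement intermittency; fattens the speed tail).
#' @param restore_gain gravity-restoring feedback, 1/s, keeping the tilt
#'   trajectory concentrated around upright as in a behaving animal.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(duration = 600, sample_rate = 250,
                              tilt_correlation_time = 2,
                              rotation_band_edges = c(1, 4, 10, 20),
                              rotation_scale = 55,
                              roll_attenuation = 0.5,
                              lever_arm = c(-0.02, 0, -0.02),
                              accel_noise_sd = 0.01,
                              gyro_noise_sd = 0.5,
                              seed = 1L,
                              slow_ratio = 0.35,
                              burst_sd = 0.7,
                              restore_gain = 0.35) {
  cfg <- list(duration = duration, sample_rate = sample_rate,
              tilt_correlation_time = tilt_correlation_time,
              rotation_band_edges = rotation_band_edges,
              rotation_scale = rotation_scale,
              roll_attenuation = roll_attenuation,
              lever_arm = as.numeric(lever_arm),
              accel_noise_sd = accel_noise_sd,
              gyro_noise_sd = gyro_noise_sd,
              seed = as.integer(seed),
              slow_ratio = slow_ratio, burst_sd = burst_sd,
              restore_gain = restore_gain)
  vals <- unlist(cfg[c("duration", "sample_rate", "tilt_correlation_time",
                       "rotation_band_edges", "rotation_scale",
                       "roll_attenuation", "lever_arm", "accel_noise_sd",
                       "gyro_noise_sd", "slow_ratio", "burst_sd",
                       "restore_gain")])
  if (!all(is.finite(vals))) stop("simulation_config: non-finite value")
  if (duration <= 0) stop("simulation_config: duration must be > 0")
  if (sample_rate <= 0) stop("simulation_config: sample_rate must be > 0")
  if (roll_attenuation <= 0 || roll_attenuation > 1)
    stop("simulation_config: roll_attenuation must be in (0, 1]")
  structure(cfg, class = "simulation_config")
}

# zero-phase FFT band-pass of a vector, pass band [lo, hi] Hz
fft_bandpass <- function(x, lo, hi, fs) {
  n <- length(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f) # two-sided frequency magnitude
  keep <- f >= lo & f <= hi
  Re(fft(fft(x) * keep, inverse = TRUE)) / n
}

# Ornstein-Uhlenbeck process with unit stationary SD, correlation time tau
ou_process <- function(n, dt, tau) {
  a <- exp(-dt / tau)
  s <- sqrt(1 - a^2)
  x <- numeric(n)
  e <- rnorm(n)
  x[1] <- e[1]
  for (i in 2:n) x[i] <- a * x[i - 1] + s * e[i]
  x
}

#' Simulate a session of head kinematics
#'
#' Builds a head-frame angular velocity series from band-limited Gaussian
#' bursts (roll attenuated) riding on a slow, gravity-restored tilt random
#' walk; integrates it exactly into a true orientation quaternion series; and
#' synthesizes the accelerometer channel as the gravity reaction plus
#' lever-arm tangential and centripetal accelerations plus white noise.
#'
#' @param config a [simulation_config()].
#' @return list with elements `kin` (a [kinematic_series()], sensor-noise
#'   included) and `truth` (class `ground_truth`: true quaternion series `q`,
#'   true `gravity_head`, noiseless `omega`, the `config`).
#' @export
simulate_head_kinematics <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  fs <- config$sample_rate
  dt <- 1 / fs
  n <- max(2L, as.integer(round(config$duration * fs)))
  t <- (seq_len(n) - 1) * dt

  # fast rotational component: 2-3 band-limited noises, burst-modulated
  edges <- config$rotation_band_edges
  nb <- length(edges) - 1
  wts <- c(1, 0.55, 0.3)[seq_len(nb)]
  fast <- matrix(0, n, 3)
  for (ax in 1:3) {
    acc <- numeric(n)
    for (b in seq_len(nb)) {
      bn <- fft_bandpass(rnorm(n), edges[b], min(edges[b + 1], fs / 2 * 0.99), fs)
      s <- sd(bn)
      if (s > 0) acc <- acc + wts[b] * bn / s
    }
    fast[, ax] <- acc / sqrt(sum(wts^2))
  }
  env <- exp(config$burst_sd * ou_process(n, dt, 0.8))
  env <- env / mean(env)
  axis_gain <- c(config$roll_attenuation, 1, 1)
  fast <- fast * env * config$rotation_scale
  fast <- sweep(fast, 2, axis_gain, "*")

  # slow tilt-driving component (OU, seconds-long correlation)
  slow_sd <- config$slow_ratio * config$rotation_scale
  slow <- cbind(ou_process(n, dt, config$tilt_correlation_time),
                ou_process(n, dt, config$tilt_correlation_time),
                ou_process(n, dt, config$tilt_correlation_time)) * slow_sd
  slow <- sweep(slow, 2, axis_gain, "*")

  sim <- cpp_simulate_orientation(fast + slow, dt, config$restore_gain,
                                  c(1, 0, 0, 0))
  omega_true <- sim$omega_deg # deg/s, includes the restoring feedback

  # ground-truth orientation: exact integration of the emitted rate series
  q_true <- cpp_integrate_gyro(omega_true, dt, c(1, 0, 0, 0))
  g_true <- cpp_rotate_vectors(q_true, matrix(c(0, 0, 1), n, 3, byrow = TRUE),
                               TRUE)

  # accelerometer: gravity reaction + lever-arm rotational accelerations
  ra <- rotation_induced_accelerations(omega_true, config$lever_arm, fs)
  acc <- g_true + ra$tangential + ra$centripetal
  if (config$accel_noise_sd > 0)
    acc <- acc + matrix(rnorm(3 * n, sd = config$accel_noise_sd), n, 3)
  omega_meas <- omega_true
  if (config$gyro_noise_sd > 0)
    omega_meas <- omega_meas + matrix(rnorm(3 * n, sd = config$gyro_noise_sd),
                                      n, 3)

  kin <- kinematic_series(t, omega_meas, acc, fs)
  truth <- structure(list(q = q_true, gravity_head = g_true,
                          omega = omega_true, t = t, config = config),
                     class = "ground_truth")
  list(kin = kin, truth = truth)
}

#' Planted tuning model of a unit
#'
#' Describes how a simulated unit's instantaneous rate depends on the true
#' kinematics.  Rotation kinds are linear in angular velocity (head- or
#' earth-frame dot product with a preferred axis, at a response lag); the
#' tilt kind is a von Mises-Fisher-shaped bump of the gravity direction; the
#' gated kind multiplies a rotational term by a gate on one gravity
#' component (on/off, or sign-reversing with `gate$mode = "reverse"`).
#'
#' @param kind one of `"rotation_head_frame"`, `"rotation_earth_frame"`,
#'   `"tilt"`, `"gated_mixed"`, `"untuned"`.
#' @param baseline_rate baseline firing rate, Hz (>= 0).
#' @param gain Hz per (deg/s) for rotation kinds; Hz at bump center for the
#'   tilt kind.
#' @param preferred_axis unit 3-vector; head frame for
#'   `rotation_head_frame`/`gated_mixed`, earth frame for
#'   `rotation_earth_frame`.
#' @param preferred_tilt unit 3-vector, head-frame gravity direction of the
#'   tilt bump.
#' @param tilt_concentration von Mises-Fisher concentration of the tilt bump.
#' @param response_lag lag between kinematics and rate, seconds (positive:
#'   firing follows movement).
#' @param isi_cv target ISI coefficient of variation (gamma renewal shape
#'   `1/isi_cv^2`).
#' @param gate for `gated_mixed`: list with `axis` in `"x"`,`"y"`,`"z"`,
#'   `sign` (+1/-1), `threshold` (g) and `mode` (`"on_off"` or `"reverse"`).
#' @return object of class `tuning_spec`.
#' @export
tuning_spec <- function(kind = c("rotation_head_frame", "rotation_earth_frame",
                                 "tilt", "gated_mixed", "untuned"),
                        baseline_rate = 40, gain = 0.2,
                        preferred_axis = c(0, 0, 1),
                        preferred_tilt = c(0, 0, 1),
                        tilt_concentration = 4,
                        response_lag = 0.04, isi_cv = 0.95,
                        gate = list(axis = "x", sign = 1, threshold = 0,
                                    mode = "on_off")) {
  kind <- match.arg(kind)
  stopifnot(baseline_rate >= 0, isi_cv > 0)
  preferred_axis <- preferred_axis / sqrt(sum(preferred_axis^2))
  preferred_tilt <- preferred_tilt / sqrt(sum(preferred_tilt^2))
  gate <- modifyList(list(axis = "x", sign = 1, threshold = 0,
                          mode = "on_off"), as.list(gate))
  structure(list(kind = kind, baseline_rate = baseline_rate, gain = gain,
                 preferred_axis = preferred_axis,
                 preferred_tilt = preferred_tilt,
                 tilt_concentration = tilt_concentration,
                 response_lag = response_lag, isi_cv = isi_cv, gate = gate),
            class = "tuning_spec")
}

# shift a series by k samples (positive k: value seen at t is the value that
# occurred k samples earlier), edge-padded
lag_shift <- function(x, k) {
  x <- rbind(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  k <- as.integer(k)
  if (k == 0) return(x)
  if (k > 0) rbind(x[rep(1L, min(k, n)), , drop = FALSE],
                   x[seq_len(max(0, n - k)), , drop = FALSE])
  else rbind(x[(-k + 1):n, , drop = FALSE],
             x[rep(n, min(-k, n)), , drop = FALSE])
}

#' Noiseless instantaneous rate of a planted unit
#'
#' @param spec a [tuning_spec()].
#' @param truth ground truth from [simulate_head_kinematics()].
#' @return numeric rate series, Hz, rectified at 0, on the kinematic grid.
#' @export
tuning_rate <- function(spec, truth) {
  stopifnot(inherits(spec, "tuning_spec"))
  n <- length(truth$t)
  fs <- 1 / (truth$t[2] - truth$t[1])
  k <- round(spec$response_lag * fs)
  g <- truth$gravity_head
  lam <- switch(spec$kind,
    untuned = rep(spec$baseline_rate, n),
    rotation_head_frame = {
      om <- lag_shift(truth$omega, k)
      spec$baseline_rate + spec$gain * drop(om %*% spec$preferred_axis)
    },
    rotation_earth_frame = {
      om_e <- cpp_rotate_vectors(truth$q, truth$omega, FALSE)
      om_e <- lag_shift(om_e, k)
      spec$baseline_rate + spec$gain * drop(om_e %*% spec$preferred_axis)
    },
    tilt = {
      gs <- lag_shift(g, k)
      d <- pmin(1, pmax(-1, drop(gs %*% spec$preferred_tilt)))
      spec$baseline_rate +
        spec$gain * exp(spec$tilt_concentration * (d - 1))
    },
    gated_mixed = {
      om <- lag_shift(truth$omega, k)
      gs <- lag_shift(g, k)
      gx <- gs[, match(spec$gate$axis, c("x", "y", "z"))]
      on <- spec$gate$sign * gx > spec$gate$threshold
      fac <- if (identical(spec$gate$mode, "reverse")) ifelse(on, 1, -1)
             else as.numeric(on)
      spec$baseline_rate + fac * spec$gain * drop(om %*% spec$preferred_axis)
    })
  pmax(0, lam)
}

#' Draw a spike train from a rate series by time-rescaled gamma renewal
#'
#' Inter-arrival times in rescaled (integrated-rate) time are gamma with
#' shape `1/isi_cv^2` and unit mean, giving exact rate control with a single
#' regularity knob (`CV = 1/sqrt(shape)`).
#'
#' @param rate nonnegative rate series, Hz, on the time grid `t`.
#' @param t uniform time grid, seconds.
#' @param isi_cv target ISI coefficient of variation.
#' @param seed optional integer seed.
#' @return numeric vector of spike times, seconds (possibly empty).
#' @export
spikes_from_rate <- function(rate, t, isi_cv = 0.95, seed = NULL) {
  stopifnot(length(rate) == length(t), all(rate >= 0))
  if (!is.null(seed)) set.seed(seed)
  dt <- t[2] - t[1]
  # trapezoid cumulative intensity
  Lam <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * dt))
  total <- Lam[length(Lam)]
  if (total <= 0) return(numeric(0))
  shape <- 1 / isi_cv^2
  draw <- function(m) rgamma(m, shape = shape, rate = shape)
  s <- cumsum(draw(ceiling(total + 4 * sqrt(total) + 20)))
  while (s[length(s)] < total)
    s <- c(s, s[length(s)] + cumsum(draw(ceiling(0.2 * total) + 20)))
  s <- s[s < total]
  if (!length(s)) return(numeric(0))
  # invert Lam (flat stretches have zero mass a.s.; tiny ramp keeps approx happy)
  Lam <- Lam + seq_along(Lam) * 1e-12
  approx(Lam, t, xout = s, ties = "ordered")$y
}

#' Simulate a unit's spike train from a planted tuning model
#'
#' @param kin a [kinematic_series()] (used for the time grid).
#' @param truth matching ground truth.
#' @param spec a [tuning_spec()].
#' @param seed optional integer seed for the spike draw.
#' @return numeric vector of spike times, seconds.
#' @export
simulate_unit <- function(kin, truth, spec, seed = NULL) {
  if (max(kin$t) - min(kin$t) < abs(spec$response_lag))
    stop("simulate_unit: kinematics shorter than the response lag")
  rate <- tuning_rate(spec, truth)
  spikes_from_rate(rate, kin$t, spec$isi_cv, seed = seed)
}
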
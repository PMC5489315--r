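# Orientation estimation and gravity decomposition of head-mounted inertial
# signals.

#' Estimate head orientation from gyroscope and accelerometer
#'
#' Quaternion complementary filter: each step propagates the orientation by
#' exact integration of the gyro increment, then tilts the estimate toward
#' the accelerometer-measured gravity direction by spherical interpolation
#' with weight `correction_gain`.  `correction_gain = 0` is pure gyro
#' integration; `correction_gain = 1` snaps the estimated gravity direction
#' to the normalized accelerometer vector.  The gravity component of
#' acceleration is the converse (conjugate) rotation of the earth-vertical
#' unit vector, scaled to 1 g; the non-gravitational component is the exact
#' residual.
#'
#' @param kin a [kinematic_series()].
#' @param correction_gain accelerometer correction weight per sample, in
#'   \[0, 1\].  The default 0.01 at 250 Hz gives a ~0.4 s tilt time
#'   constant.
#' @param q0 initial quaternion (scalar-first), or `"from-first-sample"` to
#'   initialize tilt from the first accelerometer sample with zero heading.
#' @return an [orientation_series()].
#' @export
estimate_orientation <- function(kin, correction_gain = 0.01,
                                 q0 = "from-first-sample") {
  stopifnot(inherits(kin, "kinematic_series"))
  if (!is.numeric(correction_gain) || correction_gain < 0 ||
      correction_gain > 1)
    stop("estimate_orientation: correction_gain must be in [0, 1]")
  if (identical(q0, "from-first-sample")) {
    a1 <- kin$acc[1, ]
    if (sqrt(sum(a1^2)) < 1e-6) {
      q0 <- c(1, 0, 0, 0)
    } else {
      q0 <- quat_between(a1, c(0, 0, 1))
    }
  }
  res <- cpp_orientation_filter(kin$omega, kin$acc, 1 / kin$sample_rate,
                                correction_gain, q0)
  g <- res$gravity_head # unit norm by construction, = 1 g
  orientation_series(res$q, g, kin$acc - g, kin$t)
}

#' Decompose acceleration into gravitational and non-gravitational parts
#'
#' Exact additive decomposition `acc = A^G + A^nG` with `||A^G|| = 1` g per
#' sample, using the orientation series' quaternions.
#'
#' @param kin a [kinematic_series()].
#' @param orient an [orientation_series()] aligned to `kin`.
#' @return list with n x 3 matrices `ag` and `ang` (g, head frame).
#' @export
decompose_acceleration <- function(kin, orient) {
  n <- length(kin$t)
  if (nrow(orient$q) != n)
    stop("decompose_acceleration: length mismatch between kin and orient")
  up <- matrix(c(0, 0, 1), n, 3, byrow = TRUE)
  ag <- cpp_rotate_vectors(orient$q, up, TRUE)
  list(ag = ag, ang = kin$acc - ag)
}

#' Re-express a head-frame vector series in the earth frame
#'
#' @param v n x 3 matrix, head-frame vector series.
#' @param orient an [orientation_series()] with matching length.
#' @return n x 3 matrix in earth coordinates; norms are preserved.
#' @export
rotate_to_earth_frame <- function(v, orient) {
  v <- as.matrix(v)
  if (nrow(v) != nrow(orient$q))
    stop("rotate_to_earth_frame: length mismatch")
  qn <- sqrt(rowSums(orient$q^2))
  if (any(abs(qn - 1) > 1e-6))
    stop("rotate_to_earth_frame: non-unit quaternions")
  cpp_rotate_vectors(orient$q, v, FALSE)
}

#' Welch-averaged power spectral density
#'
#' Hann-windowed, 50%-overlapping segment average of the periodogram.  No
#' detrending, so DC power is preserved.
#'
#' @param x numeric vector.
#' @param sample_rate Hz.
#' @param segment_length samples per segment (default 4 s of data).
#' @return list with `frequency` (Hz) and `psd` (power per Hz); the
#'   integral of `psd` over frequency equals the series' mean square.
#' @export
welch_psd <- function(x, sample_rate, segment_length = NULL) {
  n <- length(x)
  if (is.null(segment_length))
    segment_length <- min(n, round(4 * sample_rate))
  L <- min(segment_length, n)
  step <- max(1, floor(L / 2))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1)) # Hann
  wnorm <- sum(win^2)
  starts <- seq(1, n - L + 1, by = step)
  acc <- numeric(floor(L / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + L - 1)] * win
    p <- abs(fft(seg))^2 / (wnorm * sample_rate)
    half <- p[seq_len(floor(L / 2) + 1)]
    # fold in the negative frequencies (all but DC and Nyquist)
    idx <- 2:(length(half) - if (L %% 2 == 0) 1 else 0)
    half[idx] <- 2 * half[idx]
    acc <- acc + half
  }
  list(frequency = (seq_len(floor(L / 2) + 1) - 1) * sample_rate / L,
       psd = acc / length(starts))
}

#' Per-band power fractions of one or more channels
#'
#' @param x numeric vector or n x p matrix (channels in columns).
#' @param bands list of `c(lo, hi)` frequency intervals, Hz.
#' @param sample_rate Hz.
#' @param segment_length Welch segment length in samples (default 4 s).
#' @return list with `frequency`, `psd` (matrix), `band_power` (bands x
#'   channels) and `band_fraction` (share of each channel's total power per
#'   band).
#' @export
band_power_fractions <- function(x, bands, sample_rate,
                                 segment_length = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2 * sample_rate)
    stop("band_power_fractions: need at least 2 s of data")
  nyq <- sample_rate / 2
  bands <- lapply(bands, function(b) {
    if (length(b) != 2 || b[1] < 0 || b[2] <= b[1])
      stop("band_power_fractions: malformed band")
    if (b[1] > nyq) stop("band_power_fractions: band outside Nyquist range")
    b
  })
  psd <- NULL
  for (j in seq_len(ncol(x))) {
    w <- welch_psd(x[, j], sample_rate, segment_length)
    if (is.null(psd)) {
      freq <- w$frequency
      psd <- matrix(0, length(freq), ncol(x))
    }
    psd[, j] <- w$psd
  }
  bp <- sapply(seq_len(ncol(x)), function(j) {
    sapply(bands, function(b) sum(psd[freq >= b[1] & freq <= b[2], j]))
  })
  bp <- matrix(bp, nrow = length(bands))
  tot <- colSums(psd)
  frac <- sweep(bp, 2, ifelse(tot > 0, tot, NA_real_), "/")
  list(frequency = freq, psd = psd, band_power = bp, band_fraction = frac)
}

#' Share of acceleration power carried by each component, per band
#'
#' For each frequency band, the fraction of the total spectral density of
#' measured acceleration (summed over the three axes) attributable to the
#' gravitational and the non-gravitational component; the residual
#' cross-term is reported separately.
#'
#' @param kin a [kinematic_series()].
#' @param orient an aligned [orientation_series()].
#' @param bands list of `c(lo, hi)` intervals, Hz.
#' @return data.frame with columns `lo`, `hi`, `gravitational`,
#'   `non_gravitational`, `cross`.
#' @export
acceleration_band_fractions <- function(kin, orient,
                                        bands = list(c(0, 2), c(2, 20))) {
  fs <- kin$sample_rate
  tot <- band_power_fractions(kin$acc, bands, fs)
  ag <- band_power_fractions(orient$gravity_head, bands, fs)
  ang <- band_power_fractions(orient$nongrav_head, bands, fs)
  ptot <- rowSums(tot$band_power)
  pag <- rowSums(ag$band_power)
  pang <- rowSums(ang$band_power)
  data.frame(lo = sapply(bands, `[`, 1), hi = sapply(bands, `[`, 2),
             gravitational = pag / ptot, non_gravitational = pang / ptot,
             cross = (ptot - pag - pang) / ptot)
}

# central differences in the interior, one-sided at the ends
central_diff <- function(x, dt) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("central_diff: need at least 3 samples")
  d <- x
  d[1, ] <- (x[2, ] - x[1, ]) / dt
  d[n, ] <- (x[n, ] - x[n - 1, ]) / dt
  d[2:(n - 1), ] <- (x[3:n, ] - x[1:(n - 2), ]) / (2 * dt)
  d
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Rotation-induced linear accelerations at a lever arm
#'
#' Tangential (`omega_dot x r`) and centripetal (`omega x (omega x r)`)
#' accelerations of a point at lever arm `r` from the rotation pivot,
#' returned in g.  Angular acceleration is obtained by central differences
#' on the uniform grid.
#'
#' @param omega n x 3 angular velocity, deg/s (converted to rad/s
#'   internally).
#' @param lever_arm 3-vector, meters, pivot to sensor.
#' @param sample_rate Hz of the `omega` grid.
#' @return list of n x 3 matrices `tangential` and `centripetal` (g).
#' @export
rotation_induced_accelerations <- function(omega, lever_arm,
                                           sample_rate = 250) {
  omega <- as.matrix(omega)
  if (!all(is.finite(lever_arm)) || length(lever_arm) != 3)
    stop("rotation_induced_accelerations: lever_arm must be a finite 3-vector")
  g0 <- 9.81
  n <- nrow(omega)
  w <- omega * pi / 180 # rad/s
  r <- matrix(as.numeric(lever_arm), n, 3, byrow = TRUE)
  wd <- central_diff(w, 1 / sample_rate) # rad/s^2
  list(tangential = cross3(wd, r) / g0,
       centripetal = cross3(w, cross3(w, r)) / g0)
}

#' Kinematic derivatives and earth-frame angular velocity
#'
#' Central-difference angular acceleration (deg/s^2), time derivative of the
#' gravitational acceleration (g/s), and the angular velocity re-expressed
#' in the earth frame.
#'
#' @param kin a [kinematic_series()].
#' @param orient an aligned [orientation_series()].
#' @return list with n x 3 matrices `omega_dot`, `gravity_jerk`,
#'   `omega_earth`.
#' @export
kinematic_derivatives <- function(kin, orient) {
  if (length(kin$t) < 3) stop("kinematic_derivatives: series too short")
  dt <- 1 / kin$sample_rate
  list(omega_dot = central_diff(kin$omega, dt),
       gravity_jerk = central_diff(orient$gravity_head, dt),
       omega_earth = rotate_to_earth_frame(kin$omega, orient))
}
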
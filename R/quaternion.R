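# Quaternion helpers (scalar-first w,x,y,z).  The convention used throughout:
# q maps sensor-frame vectors into the earth frame, v_E = q v_S q*.  The
# gravity direction seen by the sensor is therefore q* e_z q (the "converse"
# rotation of earth-up).

#' Quaternion product
#'
#' Hamilton product of two quaternions (or rowwise of two n x 4 matrices),
#' scalar-first storage.
#'
#' @param a,b numeric length-4 vectors or n x 4 matrices.
#' @return length-4 vector or n x 4 matrix.
#' @export
quat_multiply <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  out <- cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
  if (nrow(out) == 1L) out <- drop(out)
  out
}

#' Quaternion conjugate
#' @param q length-4 vector or n x 4 matrix.
#' @return same shape as `q`.
#' @export
quat_conjugate <- function(q) {
  q <- rbind(q)
  out <- cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])
  if (nrow(out) == 1L) out <- drop(out)
  out
}

#' Normalize quaternions to unit norm
#' @param q length-4 vector or n x 4 matrix.
#' @return same shape as `q`.
#' @export
quat_normalize <- function(q) {
  q <- rbind(q)
  out <- q / sqrt(rowSums(q^2))
  if (nrow(out) == 1L) out <- drop(out)
  out
}

#' Axis-angle rotation quaternion
#' @param axis unit 3-vector (normalized internally).
#' @param angle rotation angle in radians.
#' @return length-4 quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Rotate 3-vectors by quaternions
#'
#' @param q length-4 vector or n x 4 matrix of unit quaternions.
#' @param v length-3 vector or n x 3 matrix.
#' @param inverse if `TRUE` apply the conjugate rotation (earth -> sensor).
#' @return rotated vectors, n x 3 matrix (or length-3 vector).
#' @export
quat_rotate <- function(q, v, inverse = FALSE) {
  q <- rbind(q); v <- rbind(v)
  if (nrow(q) == 1L && nrow(v) > 1L) q <- q[rep(1L, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1L && nrow(q) > 1L) v <- v[rep(1L, nrow(q)), , drop = FALSE]
  out <- cpp_rotate_vectors(q, v, inverse)
  if (nrow(out) == 1L) out <- drop(out)
  out
}

#' Minimal rotation mapping one direction onto another
#'
#' Returns the quaternion of the rotation about `from x to` that maps the
#' direction `from` onto `to` (both normalized internally).  Used to
#' initialize the orientation filter from the first accelerometer sample
#' (tilt only, zero heading twist).
#'
#' @param from,to 3-vectors.
#' @return length-4 quaternion.
#' @export
quat_between <- function(from, to) {
  f <- from / sqrt(sum(from^2))
  t2 <- to / sqrt(sum(to^2))
  d <- sum(f * t2)
  ax <- c(f[2] * t2[3] - f[3] * t2[2],
          f[3] * t2[1] - f[1] * t2[3],
          f[1] * t2[2] - f[2] * t2[1])
  al <- sqrt(sum(ax^2))
  if (al < 1e-12) {
    if (d > 0) return(c(1, 0, 0, 0))
    # antipodal: rotate 180 deg about any axis orthogonal to f
    o <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(f[2] * o[3] - f[3] * o[2], f[3] * o[1] - f[1] * o[3],
            f[1] * o[2] - f[2] * o[1])
    return(quat_from_axis_angle(ax, pi))
  }
  quat_from_axis_angle(ax / al, acos(max(-1, min(1, d))))
}

#' Exact integration of a gyroscope series
#'
#' Propagates a unit quaternion through a uniformly sampled body-rate series
#' using the exact quaternion exponential of the midpoint rate over each
#' step.
#'
#' @param omega_deg n x 3 matrix of angular velocity, deg/s, head frame.
#' @param dt sample interval, seconds.
#' @param q0 initial quaternion (scalar-first); default identity.
#' @return n x 4 matrix of unit quaternions (sensor -> earth).
#' @export
integrate_gyro <- function(omega_deg, dt, q0 = c(1, 0, 0, 0)) {
  stopifnot(is.matrix(omega_deg), ncol(omega_deg) == 3, dt > 0)
  cpp_integrate_gyro(omega_deg, dt, q0)
}

# angle (deg) between rows of two n x 3 direction matrices
angle_between_deg <- function(a, b) {
  a <- a / sqrt(rowSums(a^2)); b <- b / sqrt(rowSums(b^2))
  d <- pmin(1, pmax(-1, rowSums(a * b)))
  acos(d) * 180 / pi
}
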
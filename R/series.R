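# Core containers.  Lightweight S3 lists, in the style of most time-series
# neuroscience tooling: a uniform time grid plus aligned matrices.

#' Construct a kinematic series
#'
#' Synchronized head-frame angular velocity and acceleration on a uniform
#' time grid.
#'
#' @param t time stamps, seconds, strictly increasing uniform grid.
#' @param omega n x 3 matrix of angular velocity, deg/s (x roll, y pitch,
#'   z yaw; head frame, x forward, y leftward, z dorsal, right-handed).
#' @param acc n x 3 matrix of measured acceleration, g, head frame.
#' @param sample_rate sampling rate, Hz; inferred from `t` when `NULL`.
#' @return object of class `kinematic_series`.
#' @export
kinematic_series <- function(t, omega, acc, sample_rate = NULL) {
  omega <- as.matrix(omega); acc <- as.matrix(acc)
  n <- length(t)
  stopifnot(n >= 2, nrow(omega) == n, nrow(acc) == n,
            ncol(omega) == 3, ncol(acc) == 3)
  if (!all(is.finite(t)) || !all(is.finite(omega)) || !all(is.finite(acc)))
    stop("kinematic_series: non-finite values in input")
  dt <- diff(t)
  if (any(dt <= 0)) stop("kinematic_series: timestamps not strictly increasing")
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("kinematic_series: non-uniform timestamps")
  if (is.null(sample_rate)) sample_rate <- 1 / mean(dt)
  if (abs(sample_rate * mean(dt) - 1) > 1e-4)
    stop("kinematic_series: sample_rate inconsistent with timestamps")
  colnames(omega) <- c("omega_x", "omega_y", "omega_z")
  colnames(acc) <- c("acc_x", "acc_y", "acc_z")
  structure(list(t = as.numeric(t), omega = omega, acc = acc,
                 sample_rate = sample_rate),
            class = "kinematic_series")
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("<kinematic_series> %d samples @ %.6g Hz (%.1f s)\n",
              length(x$t), x$sample_rate, diff(range(x$t))))
  spd <- sqrt(rowSums(x$omega^2))
  cat(sprintf("  angular speed median %.1f deg/s, 2.5-97.5%% [%.1f, %.1f]\n",
              median(spd), quantile(spd, 0.025), quantile(spd, 0.975)))
  invisible(x)
}

#' Construct an orientation series
#'
#' Estimated (or true) sensor-to-earth rotation plus the gravity
#' decomposition of acceleration in head coordinates.
#'
#' @param q n x 4 matrix of unit quaternions (scalar-first, sensor -> earth).
#' @param gravity_head n x 3 gravitational acceleration, g, head frame;
#'   unit norm per sample.
#' @param nongrav_head n x 3 non-gravitational residual, g, head frame.
#' @param t time stamps matching the source kinematics.
#' @return object of class `orientation_series`.
#' @export
orientation_series <- function(q, gravity_head, nongrav_head, t) {
  q <- as.matrix(q); gravity_head <- as.matrix(gravity_head)
  nongrav_head <- as.matrix(nongrav_head)
  n <- length(t)
  stopifnot(nrow(q) == n, ncol(q) == 4, nrow(gravity_head) == n,
            nrow(nongrav_head) == n)
  qn <- sqrt(rowSums(q^2))
  if (any(abs(qn - 1) > 1e-6)) stop("orientation_series: non-unit quaternions")
  structure(list(q = q, gravity_head = gravity_head,
                 nongrav_head = nongrav_head, t = as.numeric(t)),
            class = "orientation_series")
}

#' @export
print.orientation_series <- function(x, ...) {
  tilt <- acos(pmin(1, pmax(-1, x$gravity_head[, 3]))) * 180 / pi
  cat(sprintf("<orientation_series> %d samples, tilt median %.1f deg (max %.1f)\n",
              nrow(x$q), median(tilt), max(tilt)))
  invisible(x)
}

#' Assemble the inertial channel matrix
#'
#' Builds the named channel matrix used by the resampling estimator and the
#' linear models: angular velocity, raw acceleration and (when an
#' orientation is supplied) its gravitational / non-gravitational
#' components.
#'
#' @param kin a [kinematic_series()].
#' @param orient optional [orientation_series()] aligned to `kin`.
#' @return n x p numeric matrix with columns `omega_x..z`, `acc_x..z` and,
#'   with `orient`, `ag_x..z`, `ang_x..z`.
#' @export
inertial_channels <- function(kin, orient = NULL) {
  out <- cbind(kin$omega, kin$acc)
  if (!is.null(orient)) {
    if (nrow(orient$q) != length(kin$t))
      stop("inertial_channels: orientation not aligned to kinematics")
    ag <- orient$gravity_head; ang <- orient$nongrav_head
    colnames(ag) <- c("ag_x", "ag_y", "ag_z")
    colnames(ang) <- c("ang_x", "ang_y", "ang_z")
    out <- cbind(out, ag, ang)
  }
  out
}

#' Expand channel-set shorthand
#'
#' `"omega"`, `"acc"`, `"ag"`, `"ang"` expand to their three component
#' channels; full channel names pass through.
#'
#' @param sets character vector of shorthands and/or channel names.
#' @return character vector of channel names.
#' @export
channel_set <- function(sets) {
  expand <- function(s) {
    if (s %in% c("omega", "acc", "ag", "ang")) paste0(s, c("_x", "_y", "_z"))
    else s
  }
  unique(unlist(lapply(sets, expand)))
}
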
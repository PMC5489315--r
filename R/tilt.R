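# Head-tilt space analyses: spherical rate maps, equal-area projection, and
# the tilt-stability of rotational sensitivity.

#' Quasi-uniform grid of points on the unit sphere
#'
#' Fibonacci lattice: deterministic, quasi-uniform coverage.
#'
#' @param n number of points (default 642).
#' @param cap_radius angular radius, degrees, of the cap associated with
#'   each point in map computations.
#' @return object of class `sphere_grid` with `points` (n x 3 unit vectors)
#'   and `cap_radius`.
#' @export
sphere_grid <- function(n = 642, cap_radius = 20) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i # golden-angle azimuth
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  structure(list(points = pts, cap_radius = cap_radius),
            class = "sphere_grid")
}

#' Tilt-dependent firing-rate map on the sphere
#'
#' For every grid point, the mean instantaneous rate over samples whose
#' gravity direction (head coordinates) lies within `cap_radius` of the
#' point.  Caps overlap, which smooths the map; the map CV is the
#' coefficient of variation of rates across sufficiently occupied points.
#'
#' @param fr rate series, Hz.
#' @param gravity_head n x 3 gravity direction series (unit norm).
#' @param grid a [sphere_grid()].
#' @param min_occupancy minimum samples per cap (default 500, i.e. 2 s at
#'   250 Hz).
#' @return object of class `tilt_rate_map`: `mean_rate`, `occupancy` (per
#'   point; rate `NA` below `min_occupancy`), `cv`, `grid`.
#' @export
tilt_rate_map <- function(fr, gravity_head, grid = sphere_grid(),
                          min_occupancy = 500) {
  g <- as.matrix(gravity_head)
  gn <- sqrt(rowSums(g^2))
  if (any(abs(gn - 1) > 1e-3))
    stop("tilt_rate_map: gravity_head must be unit-norm directions")
  g <- g / gn
  cosr <- cos(grid$cap_radius * pi / 180)
  np <- nrow(grid$points)
  occ <- integer(np)
  mr <- rep(NA_real_, np)
  for (j in seq_len(np)) {
    inside <- drop(g %*% grid$points[j, ]) >= cosr
    occ[j] <- sum(inside)
    if (occ[j] >= min_occupancy) mr[j] <- mean(fr[inside])
  }
  vals <- mr[is.finite(mr)]
  if (!length(vals)) stop("tilt_rate_map: no occupied grid points")
  cv <- sd(vals) / mean(vals)
  structure(list(mean_rate = mr, occupancy = occ, cv = cv, grid = grid),
            class = "tilt_rate_map")
}

#' @export
print.tilt_rate_map <- function(x, ...) {
  cat(sprintf("<tilt_rate_map> %d/%d occupied points, rate CV %.3f\n",
              sum(is.finite(x$mean_rate)), length(x$mean_rate), x$cv))
  invisible(x)
}

#' Lambert azimuthal equal-area projection
#'
#' Projects unit-sphere points to the plane around `pole`: planar radius
#' `2 sin(theta / 2)` for angular distance `theta` from the pole, azimuth
#' preserved.  Areas are preserved; the equator maps to radius `sqrt(2)`
#' and the antipode to the boundary circle of radius 2.
#'
#' @param points n x 3 matrix of unit vectors (or length-3 vector).
#' @param pole unit 3-vector at the projection center (default +z).
#' @return n x 2 matrix of planar coordinates.
#' @export
lambert_project <- function(points, pole = c(0, 0, 1)) {
  p <- rbind(points)
  pole <- pole / sqrt(sum(pole^2))
  # deterministic orthonormal basis perpendicular to the pole
  helper <- if (abs(pole[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- helper - sum(helper * pole) * pole
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(pole[2] * e1[3] - pole[3] * e1[2],
          pole[3] * e1[1] - pole[1] * e1[3],
          pole[1] * e1[2] - pole[2] * e1[1])
  z <- drop(p %*% pole)
  x <- drop(p %*% e1)
  y <- drop(p %*% e2)
  theta <- acos(pmin(1, pmax(-1, z)))
  if (any(theta > pi - 1e-9))
    warning("lambert_project: antipode of the pole maps to the boundary circle")
  rr <- 2 * sin(theta / 2)
  az <- atan2(y, x)
  horiz <- sqrt(x^2 + y^2)
  az[horiz < 1e-12] <- 0
  cbind(rr * cos(az), rr * sin(az))
}

#' Tilt-stability index of rotational sensitivity
#'
#' Sensitivity vectors are fitted separately for the two hemifields of one
#' gravity component (`a^G_axis > threshold` vs `< -threshold`), at every
#' lag of `lag_grid`; sigma is the gain-weighted mean (weights: the smaller
#' of the two hemifield gains per lag) of the cosine between the two
#' hemifield vectors.  1 means the preferred rotation axis is identical for
#' opposite head orientations; -1 means it reverses.
#'
#' @param fr rate series, Hz.
#' @param omega n x 3 head-frame angular velocity, deg/s.
#' @param gravity_head n x 3 gravity direction series.
#' @param axis `"x"` or `"y"` (the tilt component defining the hemifields).
#' @param sample_rate Hz.
#' @param lag_grid lags, seconds.
#' @param threshold hemifield threshold, g.
#' @param min_samples minimum samples per hemifield.
#' @return object of class `stability_index`: `sigma`, `axis`, `per_lag`
#'   data.frame (`lag`, `cosine`, `gain_pos`, `gain_neg`).
#' @export
stability_index <- function(fr, omega, gravity_head, axis = c("x", "y"),
                            sample_rate = 250,
                            lag_grid = seq(-0.2, 0.2, by = 0.02),
                            threshold = 0.25, min_samples = 1000) {
  axis <- match.arg(axis)
  ai <- match(axis, c("x", "y"))
  gcomp <- gravity_head[, ai]
  pos <- which(gcomp > threshold)
  neg <- which(gcomp < -threshold)
  if (length(pos) < min_samples || length(neg) < min_samples)
    return(structure(list(sigma = NA_real_, axis = axis, per_lag = NULL,
                          n_pos = length(pos), n_neg = length(neg)),
                     class = "stability_index"))
  fit_sub <- function(idx, off) {
    n <- length(fr)
    tgt <- idx + off
    ok <- tgt >= 1 & tgt <= n
    X <- cbind(1, omega[idx[ok], , drop = FALSE])
    fit <- lm.fit(X, fr[tgt[ok]])
    v <- fit$coefficients[-1]
    list(v = v, gain = sqrt(sum(v^2)))
  }
  per <- lapply(lag_grid, function(lag) {
    off <- as.integer(round(lag * sample_rate))
    fp <- fit_sub(pos, off)
    fn <- fit_sub(neg, off)
    cosv <- sum(fp$v * fn$v) / (fp$gain * fn$gain)
    data.frame(lag = lag, cosine = cosv, gain_pos = fp$gain,
               gain_neg = fn$gain)
  })
  per <- do.call(rbind, per)
  wts <- pmin(per$gain_pos, per$gain_neg)
  sigma <- sum(wts * per$cosine) / sum(wts)
  structure(list(sigma = sigma, axis = axis, per_lag = per,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "stability_index")
}

#' @export
print.stability_index <- function(x, ...) {
  cat(sprintf("<stability_index> sigma_%s = %.3f (n+ %d, n- %d)\n",
              x$axis, x$sigma, x$n_pos, x$n_neg))
  invisible(x)
}
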
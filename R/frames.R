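# Head-bound vs gravity-anchored reference frame of rotational tuning:
# sensitivity vectors fitted per head-tilt region, in head and earth
# coordinates, and the collinearity of those vectors across tilt space.

#' Tilt-binned sensitivity field in head and earth coordinates
#'
#' For every tilt cap (grid point of head-tilt space) with enough samples,
#' fits the rotational sensitivity vector twice -- against head-frame and
#' against earth-frame angular velocity -- at a fixed lag.  Vector
#' significance per cap and frame is assessed against circularly
#' time-shifted rate series (gain > shuffle mean + 2 SD).
#'
#' @param fr rate series, Hz.
#' @param omega_head n x 3 head-frame angular velocity, deg/s.
#' @param omega_earth n x 3 earth-frame angular velocity (from
#'   [rotate_to_earth_frame()] with the same orientation series that
#'   produced `gravity_head`).
#' @param gravity_head n x 3 gravity direction series, head frame.
#' @param grid a [sphere_grid()] over head-tilt space.
#' @param lag seconds (the unit's optimal lag).
#' @param sample_rate Hz.
#' @param min_occupancy minimum samples per cap.
#' @param n_shuffles circular-shift iterations for per-cap significance
#'   (0 disables the test; all fitted vectors are then kept).
#' @param seed integer seed.
#' @param min_shift minimum shuffle offset, seconds.
#' @return object of class `sensitivity_field`: per grid point, internal and
#'   external vectors with gains, elevations (deg) and significance flags,
#'   plus `occupancy` and the `grid`.
#' @export
local_sensitivity_field <- function(fr, omega_head, omega_earth,
                                    gravity_head, grid = sphere_grid(),
                                    lag = 0, sample_rate = 250,
                                    min_occupancy = 500, n_shuffles = 50,
                                    seed = 1L, min_shift = 10) {
  n <- length(fr)
  g <- as.matrix(gravity_head)
  g <- g / sqrt(rowSums(g^2))
  cosr <- cos(grid$cap_radius * pi / 180)
  np <- nrow(grid$points)
  off <- as.integer(round(lag * sample_rate))
  occ <- integer(np)
  vint <- vext <- matrix(NA_real_, np, 3)
  gint <- gext <- rep(NA_real_, np)
  sint <- sext <- rep(NA, np)
  shuffled <- NULL
  if (n_shuffles > 0) {
    set.seed(seed)
    ks <- sample.int(n - 2 * round(min_shift * sample_rate), n_shuffles,
                     replace = TRUE) + round(min_shift * sample_rate)
    shuffled <- vapply(ks, function(k) circular_shift_series(fr, k),
                       numeric(n))
  }
  fit_gain <- function(X, y) {
    fit <- lm.fit(X, y)
    v <- fit$coefficients[-1]
    list(v = unname(v), gain = sqrt(sum(v^2)))
  }
  for (j in seq_len(np)) {
    idx <- which(drop(g %*% grid$points[j, ]) >= cosr)
    tgt <- idx + off
    ok <- tgt >= 1 & tgt <= n
    idx <- idx[ok]; tgt <- tgt[ok]
    occ[j] <- length(idx)
    if (occ[j] < min_occupancy) next
    Xi <- cbind(1, omega_head[idx, , drop = FALSE])
    Xe <- cbind(1, omega_earth[idx, , drop = FALSE])
    y <- fr[tgt]
    fi <- fit_gain(Xi, y)
    fe <- fit_gain(Xe, y)
    vint[j, ] <- fi$v; gint[j] <- fi$gain
    vext[j, ] <- fe$v; gext[j] <- fe$gain
    if (!is.null(shuffled)) {
      Ys <- shuffled[tgt, , drop = FALSE]
      shg <- function(X) {
        B <- tcrossprod(solve(crossprod(X)), X) %*% Ys
        sqrt(colSums(B[-1, , drop = FALSE]^2))
      }
      si <- shg(Xi); se <- shg(Xe)
      sint[j] <- fi$gain > mean(si) + 2 * sd(si)
      sext[j] <- fe$gain > mean(se) + 2 * sd(se)
    } else {
      sint[j] <- sext[j] <- TRUE
    }
  }
  elev <- function(v) {
    gn <- sqrt(rowSums(v^2))
    asin(pmin(1, pmax(-1, v[, 3] / gn))) * 180 / pi
  }
  structure(list(grid = grid, occupancy = occ,
                 internal = vint, external = vext,
                 gain_internal = gint, gain_external = gext,
                 sig_internal = sint, sig_external = sext,
                 elevation_internal = elev(vint),
                 elevation_external = elev(vext),
                 lag = lag),
            class = "sensitivity_field")
}

#' @export
print.sensitivity_field <- function(x, ...) {
  occ <- sum(is.finite(x$gain_internal))
  cat(sprintf("<sensitivity_field> %d occupied tilt caps (of %d); %d/%d significant internal/external\n",
              occ, length(x$occupancy), sum(x$sig_internal, na.rm = TRUE),
              sum(x$sig_external, na.rm = TRUE)))
  invisible(x)
}

#' Collinearity of sensitivity vectors vs tilt separation
#'
#' For every pair of occupied (and, by default, significant) tilt caps:
#' `phi` is the angular distance between the two tilt positions on the
#' sphere and `S` the dot product of the two normalized sensitivity vectors
#' in the chosen frame; `S` is averaged within `phi` bins.
#'
#' @param field a [local_sensitivity_field()] result.
#' @param frame `"internal"` or `"external"`.
#' @param phi_bin_width degrees.
#' @param require_significant drop vectors failing the per-cap shuffle test
#'   (noise vectors have random directions and bias S toward 0).
#' @return object of class `collinearity_profile`: `phi_centers`, `S`,
#'   `n_pairs`, `frame`.
#' @export
collinearity_profile <- function(field, frame = c("internal", "external"),
                                 phi_bin_width = 10,
                                 require_significant = TRUE) {
  frame <- match.arg(frame)
  v <- if (frame == "internal") field$internal else field$external
  sig <- if (frame == "internal") field$sig_internal else field$sig_external
  keep <- which(is.finite(v[, 1]) & (!require_significant | (sig %in% TRUE)))
  if (length(keep) < 3)
    stop("collinearity_profile: fewer than 3 occupied tilt caps")
  pts <- field$grid$points[keep, , drop = FALSE]
  vv <- v[keep, , drop = FALSE]
  vv <- vv / sqrt(rowSums(vv^2))
  cphi <- pts %*% t(pts)
  cS <- vv %*% t(vv)
  iu <- upper.tri(cphi)
  phi <- acos(pmin(1, pmax(-1, cphi[iu]))) * 180 / pi
  S <- cS[iu]
  edges <- seq(0, 180, by = phi_bin_width)
  bin <- findInterval(phi, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1
  nb <- length(edges) - 1
  cnt <- tabulate(bin, nbins = nb)
  sm <- numeric(nb)
  sm[sort(unique(bin))] <- rowsum(S, bin)[, 1]
  structure(list(phi_centers = (edges[-1] + edges[-(nb + 1)]) / 2,
                 S = ifelse(cnt > 0, sm / pmax(cnt, 1L), NA_real_),
                 n_pairs = cnt, frame = frame,
                 phi_bin_width = phi_bin_width),
            class = "collinearity_profile")
}

#' Classify the reference frame of a unit's rotational tuning
#'
#' `Delta S` is the mean difference between external and internal
#' collinearity over tilt separations in the decision band (80-100 deg by
#' default).  `Delta S > cutoff` labels the unit external (gravity-
#' anchored), `< -cutoff` internal (head-bound), otherwise unclassified.
#'
#' @param profile_internal,profile_external [collinearity_profile()] results
#'   with identical binning.
#' @param band degrees, `c(lo, hi)`.
#' @param cutoff decision threshold on `Delta S`.
#' @return object of class `frame_classification`: `label`, `delta_s`,
#'   `reason` (when unclassified for lack of data).
#' @export
classify_reference_frame <- function(profile_internal, profile_external,
                                     band = c(80, 100), cutoff = 0.5) {
  stopifnot(identical(profile_internal$phi_centers,
                      profile_external$phi_centers))
  ctr <- profile_internal$phi_centers
  inband <- ctr >= band[1] & ctr <= band[2]
  ds <- profile_external$S[inband] - profile_internal$S[inband]
  ds <- ds[is.finite(ds)]
  if (!length(ds))
    return(structure(list(label = "unclassified", delta_s = NA_real_,
                          reason = "decision band empty"),
                     class = "frame_classification"))
  delta_s <- mean(ds)
  label <- if (delta_s > cutoff) "external"
           else if (delta_s < -cutoff) "internal"
           else "unclassified"
  structure(list(label = label, delta_s = delta_s, reason = NULL),
            class = "frame_classification")
}

#' @export
print.frame_classification <- function(x, ...) {
  cat(sprintf("<frame_classification> %s (Delta S = %.3f)\n", x$label,
              x$delta_s))
  invisible(x)
}
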
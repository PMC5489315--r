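# Lag-dependent linear rotational tuning: sensitivity vectors, gain-vs-lag
# curves with shuffle significance, and inertio-temporal receptive fields.

# OLS of fr(t + lag) on x(t); returns list(coef = c(intercept, slopes), ok)
ols_at_lag <- function(fr, x, off) {
  n <- length(fr)
  if (off >= 0) {
    rows <- seq_len(n - off)
    y <- fr[rows + off]
  } else {
    rows <- (1 - off):n
    y <- fr[rows + off]
  }
  X <- cbind(1, x[rows, , drop = FALSE])
  fit <- lm.fit(X, y)
  ok <- fit$rank == ncol(X)
  list(coef = fit$coefficients, ok = ok, n = length(rows))
}

#' Fit a rotational sensitivity vector at one lag
#'
#' Ordinary least squares `FR(t + lag) = c + lambda . omega(t)`.  The
#' coefficient vector is the unit's rotation sensitivity vector at that lag;
#' its Euclidean norm is the gain, in Hz per (deg/s) (equivalently
#' deg^-1).
#'
#' @param fr instantaneous rate series, Hz, on the uniform grid.
#' @param omega n x 3 angular velocity, deg/s (head or earth frame).
#' @param lag seconds (positive: firing follows movement).
#' @param sample_rate Hz.
#' @return object of class `sensitivity_vector`: `components`, `gain`,
#'   `lag`, `intercept`, `ok` (FALSE for rank-deficient designs),
#'   `significant` (NA until tested).
#' @export
fit_sensitivity_at_lag <- function(fr, omega, lag, sample_rate = 250) {
  omega <- as.matrix(omega)
  off <- as.integer(round(lag * sample_rate))
  fit <- ols_at_lag(fr, omega, off)
  comp <- fit$coef[-1]
  if (!fit$ok) {
    warning("fit_sensitivity_at_lag: rank-deficient design; vector undefined")
    comp <- rep(NA_real_, ncol(omega))
  }
  structure(list(components = unname(comp),
                 gain = if (fit$ok) sqrt(sum(comp^2)) else NA_real_,
                 lag = lag, intercept = unname(fit$coef[1]),
                 n = fit$n, ok = fit$ok, significant = NA),
            class = "sensitivity_vector")
}

#' @export
print.sensitivity_vector <- function(x, ...) {
  cat(sprintf("<sensitivity_vector> gain %.4f deg^-1 at lag %+.0f ms, components (%.3f, %.3f, %.3f)\n",
              x$gain, 1000 * x$lag, x$components[1], x$components[2],
              x$components[3]))
  invisible(x)
}

# circular shift of a series by k samples
circular_shift_series <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) x else c(x[(n - k + 1):n], x[1:(n - k)])
}

#' Rotational gain as a function of lag, with shuffle band
#'
#' Fits the sensitivity vector at every lag of the grid; the optimal lag
#' maximizes the gain.  Significance compares the peak gain against gains
#' obtained from circularly time-shifted rate series (mean + 2 SD band).
#'
#' @param fr rate series, Hz.
#' @param omega n x 3 angular velocity, deg/s.
#' @param sample_rate Hz.
#' @param lag_grid lags, seconds (within +-1 s).
#' @param n_shuffles circular-shift iterations for the significance band.
#' @param seed integer seed for the shuffle offsets.
#' @param min_shift minimum shuffle offset, seconds.
#' @return object of class `gain_lag_curve`: `lags`, `gains`, `vectors`
#'   (L x 3), `intercepts`, `optimal_lag`, `optimal` (the
#'   [fit_sensitivity_at_lag()] result at the peak), `shuffle_mean`,
#'   `shuffle_sd`, `significant`.
#' @export
gain_lag_curve <- function(fr, omega, sample_rate = 250,
                           lag_grid = seq(-0.5, 0.5, by = 0.02),
                           n_shuffles = 100, seed = 1L, min_shift = 10) {
  if (any(abs(lag_grid) > 1 + 1e-9))
    stop("gain_lag_curve: lag grid must lie within +-1 s")
  omega <- as.matrix(omega)
  n <- length(fr)
  L <- length(lag_grid)
  gains <- numeric(L)
  vectors <- matrix(NA_real_, L, 3)
  intercepts <- numeric(L)
  for (l in seq_len(L)) {
    sv <- fit_sensitivity_at_lag(fr, omega, lag_grid[l], sample_rate)
    gains[l] <- sv$gain
    vectors[l, ] <- sv$components
    intercepts[l] <- sv$intercept
  }
  best <- which.max(gains)
  # shuffle band: gains of circularly shifted rate series (full wrap, so a
  # single alignment represents every lag)
  sh <- NULL
  if (n_shuffles > 0) {
    set.seed(seed)
    X <- cbind(1, omega)
    XtXi <- solve(crossprod(X))
    P <- tcrossprod(XtXi, X) # 4 x n
    offs <- sample.int(n - 2 * round(min_shift * sample_rate),
                       n_shuffles, replace = TRUE) +
      round(min_shift * sample_rate)
    Y <- vapply(offs, function(k) circular_shift_series(fr, k), numeric(n))
    B <- P %*% Y # 4 x n_shuffles
    sh <- sqrt(colSums(B[-1, , drop = FALSE]^2))
  }
  shuffle_mean <- if (is.null(sh)) NA_real_ else mean(sh)
  shuffle_sd <- if (is.null(sh)) NA_real_ else sd(sh)
  significant <- if (is.null(sh)) NA else
    gains[best] > shuffle_mean + 2 * shuffle_sd
  opt <- structure(list(components = vectors[best, ], gain = gains[best],
                        lag = lag_grid[best], intercept = intercepts[best],
                        ok = TRUE, significant = significant),
                   class = "sensitivity_vector")
  structure(list(lags = lag_grid, gains = gains, vectors = vectors,
                 intercepts = intercepts, optimal_lag = lag_grid[best],
                 optimal = opt, shuffle_mean = shuffle_mean,
                 shuffle_sd = shuffle_sd, significant = significant),
            class = "gain_lag_curve")
}

#' @export
print.gain_lag_curve <- function(x, ...) {
  cat(sprintf("<gain_lag_curve> peak gain %.4f deg^-1 at %+.0f ms (%ssignificant; shuffle %.4f +- %.4f)\n",
              max(x$gains), 1000 * x$optimal_lag,
              if (isTRUE(x$significant)) "" else "not ",
              x$shuffle_mean, x$shuffle_sd))
  invisible(x)
}

#' Inertio-temporal receptive field
#'
#' Mean firing rate as a function of the value of one kinematic channel and
#' of the lag: cell (b, l) averages `FR(t + lag_l)` over samples where
#' `channel(t)` falls in bin b and the optional condition holds.
#'
#' @param fr rate series, Hz.
#' @param channel kinematic channel values on the same grid (e.g. yaw
#'   velocity), any units.
#' @param sample_rate Hz.
#' @param value_bins bin edges for the channel; default 20 bins spanning the
#'   1st-99th percentile.
#' @param lag_grid lags, seconds.
#' @param condition optional logical vector on the grid (e.g. nose-up
#'   samples); `FALSE`/`NA` samples are excluded.
#' @param min_occupancy cells with fewer samples are masked (`NA`).
#' @return object of class `receptive_field_2d`: `value_bins`, `centers`,
#'   `lags`, `mean_rate` (bins x lags), `occupancy`.
#' @export
inertio_temporal_rf <- function(fr, channel, sample_rate = 250,
                                value_bins = NULL,
                                lag_grid = seq(-0.5, 0.5, by = 0.02),
                                condition = NULL, min_occupancy = 50) {
  n <- length(fr)
  if (is.null(value_bins)) {
    qs <- quantile(channel, c(0.01, 0.99), names = FALSE)
    value_bins <- seq(qs[1], qs[2], length.out = 21)
  }
  nb <- length(value_bins) - 1
  bin <- findInterval(channel, value_bins, rightmost.closed = TRUE)
  valid0 <- bin >= 1 & bin <= nb
  if (!is.null(condition)) valid0 <- valid0 & !is.na(condition) & condition
  if (!any(valid0)) {
    mr <- matrix(NA_real_, nb, length(lag_grid))
    occ <- matrix(0L, nb, length(lag_grid))
    return(structure(list(value_bins = value_bins,
                          centers = (value_bins[-1] + value_bins[-nb - 1]) / 2,
                          lags = lag_grid, mean_rate = mr, occupancy = occ),
                     class = "receptive_field_2d"))
  }
  L <- length(lag_grid)
  mr <- matrix(NA_real_, nb, L)
  occ <- matrix(0L, nb, L)
  idx <- seq_len(n)
  for (l in seq_len(L)) {
    off <- as.integer(round(lag_grid[l] * sample_rate))
    tgt <- idx + off
    ok <- valid0 & tgt >= 1 & tgt <= n
    b <- bin[ok]
    y <- fr[tgt[ok]]
    cnt <- tabulate(b, nbins = nb)
    s <- numeric(nb)
    s[sort(unique(b))] <- rowsum(y, b)[, 1]
    occ[, l] <- cnt
    m <- ifelse(cnt >= min_occupancy, s / pmax(cnt, 1L), NA_real_)
    mr[, l] <- m
  }
  structure(list(value_bins = value_bins,
                 centers = (value_bins[-1] + value_bins[-(nb + 1)]) / 2,
                 lags = lag_grid, mean_rate = mr, occupancy = occ),
            class = "receptive_field_2d")
}

#' Slope of the rate-vs-value regression per lag of a receptive field
#'
#' Regresses cell mean rates against bin centers, per lag; the slope at the
#' optimal lag approximates the fitted sensitivity component for that
#' channel.
#'
#' @param rf a `receptive_field_2d`.
#' @return numeric vector of slopes (Hz per channel unit), one per lag.
#' @export
rf_slopes <- function(rf) {
  vapply(seq_along(rf$lags), function(l) {
    y <- rf$mean_rate[, l]
    ok <- is.finite(y)
    if (sum(ok) < 3) return(NA_real_)
    x <- rf$centers[ok]
    cov(x, y[ok]) / var(x)
  }, numeric(1))
}
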
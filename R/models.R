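# Benchmarks of the model-free estimator against global and tilt-local
# linear models of firing rate.

#' Global linear model of firing rate on inertial regressors
#'
#' OLS over the whole recording at a fixed lag, with the chosen regressor
#' blocks among angular velocity (`omega`), angular acceleration
#' (`omega_dot`), gravitational acceleration (`ag`) and its time derivative
#' (`ag_dot`).
#'
#' @param fr rate series, Hz.
#' @param regressors named list of n x 3 matrices: `omega`, `omega_dot`,
#'   `ag`, `ag_dot` (only the blocks named in `set` are required).
#' @param set character vector of regressor block names.
#' @param lag seconds.
#' @param sample_rate Hz.
#' @return object of class `linear_model_result`: `coefficients` (named
#'   list of blocks + `intercept`), `r2`, `set`, `lag`.
#' @export
global_linear_fit <- function(fr, regressors, set = c("omega", "ag"),
                              lag = 0, sample_rate = 250) {
  stopifnot(length(set) >= 1, all(set %in% names(regressors)))
  n <- length(fr)
  off <- as.integer(round(lag * sample_rate))
  rows <- if (off >= 0) seq_len(n - off) else (1 - off):n
  y <- fr[rows + off]
  X <- do.call(cbind, lapply(set, function(s)
    as.matrix(regressors[[s]])[rows, , drop = FALSE]))
  X <- cbind(1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("global_linear_fit: collinear design; minimum-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  } else {
    beta <- qr.coef(qrX, y)
  }
  pred <- drop(X %*% beta)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum((y - pred)^2) / sst else 0
  coefs <- list(intercept = beta[1])
  pos <- 2
  for (s in set) {
    k <- ncol(as.matrix(regressors[[s]]))
    coefs[[s]] <- unname(beta[pos:(pos + k - 1)])
    pos <- pos + k
  }
  structure(list(coefficients = coefs, r2 = r2, set = set, lag = lag),
            class = "linear_model_result")
}

#' Pooled coefficient of determination of tilt-local linear models
#'
#' Each sample is assigned to the nearest occupied tilt cap of the field
#' (disjoint partition, limited to `max_angle` of an occupied point) and
#' predicted by that cap's local head-frame rotational fit; the pooled
#' r^2 over all assigned samples is returned.  Per-cell intercepts absorb
#' any tilt-dependent baseline.
#'
#' @param field a [local_sensitivity_field()] result.
#' @param fr rate series, Hz.
#' @param omega n x 3 head-frame angular velocity, deg/s.
#' @param gravity_head n x 3 gravity direction series.
#' @param sample_rate Hz.
#' @param max_angle degrees; samples farther than this from every occupied
#'   cap are left unassigned (default: the field's cap radius).
#' @return list with `r2`, `n_assigned`, `n_unassigned`.
#' @export
local_linear_r2 <- function(field, fr, omega, gravity_head,
                            sample_rate = 250, max_angle = NULL) {
  n <- length(fr)
  occ <- which(is.finite(field$gain_internal))
  if (!length(occ)) stop("local_linear_r2: field has no occupied caps")
  if (is.null(max_angle)) max_angle <- field$grid$cap_radius
  g <- as.matrix(gravity_head)
  g <- g / sqrt(rowSums(g^2))
  pts <- field$grid$points[occ, , drop = FALSE]
  # nearest occupied cap per sample
  best <- rep(NA_integer_, n)
  bestd <- rep(-2, n)
  for (jj in seq_along(occ)) {
    d <- drop(g %*% pts[jj, ])
    upd <- d > bestd
    best[upd] <- jj
    bestd[upd] <- d[upd]
  }
  assigned <- bestd >= cos(max_angle * pi / 180)
  off <- as.integer(round(field$lag * sample_rate))
  idx <- which(assigned)
  tgt <- idx + off
  ok <- tgt >= 1 & tgt <= n
  idx <- idx[ok]; tgt <- tgt[ok]
  # refit per cell on the disjoint partition
  pred <- rep(NA_real_, length(idx))
  y <- fr[tgt]
  for (jj in seq_along(occ)) {
    sel <- best[idx] == jj
    if (sum(sel) < 8) next
    X <- cbind(1, omega[idx[sel], , drop = FALSE])
    fit <- lm.fit(X, y[sel])
    pred[sel] <- drop(X %*% fit$coefficients)
  }
  use <- is.finite(pred)
  sst <- sum((y[use] - mean(y[use]))^2)
  r2 <- if (sst > 0) 1 - sum((y[use] - pred[use])^2) / sst else 0
  list(r2 = r2, n_assigned = sum(use), n_unassigned = n - sum(use))
}

#' Paired comparison of per-unit performance columns
#'
#' Paired Wilcoxon signed-rank test between two columns of a per-unit
#' comparison table, plus medians and effect direction.  A one-sample
#' Wilcoxon against 0 is available via `b = NULL`.
#'
#' @param a,b numeric vectors (per-unit values, aligned); `b = NULL` tests
#'   `a` against 0.
#' @return list with `p_value`, `median_a`, `median_b`, `direction`
#'   (`"a>b"`, `"b>a"` or `"tie"`), `n`.
#' @export
paired_comparison <- function(a, b = NULL) {
  if (is.null(b)) {
    ok <- is.finite(a)
    if (sum(ok) < 1 || all(a[ok] == 0))
      return(list(p_value = NA_real_, median_a = median(a[ok]),
                  median_b = 0, direction = "tie", n = sum(ok)))
    tst <- suppressWarnings(wilcox.test(a[ok], mu = 0))
    return(list(p_value = tst$p.value, median_a = median(a[ok]),
                median_b = 0,
                direction = if (median(a[ok]) > 0) "a>b" else "b>a",
                n = sum(ok)))
  }
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 6) stop("paired_comparison: need at least 6 paired units")
  d <- a[ok] - b[ok]
  if (all(d == 0)) # ties only: no detectable difference
    return(list(p_value = 1, median_a = median(a[ok]),
                median_b = median(b[ok]), direction = "tie", n = sum(ok),
                ties_only = TRUE))
  tst <- suppressWarnings(wilcox.test(a[ok], b[ok], paired = TRUE))
  list(p_value = tst$p.value, median_a = median(a[ok]),
       median_b = median(b[ok]),
       direction = if (median(d) > 0) "a>b"
                   else if (median(d) < 0) "b>a" else "tie",
       n = sum(ok))
}
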
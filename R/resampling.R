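# Model-free resampling estimate of movement-driven firing rate.  The
# estimate at sample i is the mean instantaneous rate observed at reference
# samples whose inertial parameters lie within a distance d (Euclidean on
# z-scored channels) and that are temporally distant (|t_j - t_i| > w when
# query and reference come from the same recording).

#' Parameter-space definition for the resampling estimator
#'
#' @param channels character vector of channel names (see
#'   [inertial_channels()]) or shorthands (`"omega"`, `"ag"`, ...).
#' @param d neighbor radius in z-scored units; `NULL` (default) tunes it per
#'   recording so the median neighbor count equals `target_neighbors`.
#' @param w temporal exclusion half-window, seconds, applied when query and
#'   reference are the same recording.
#' @param lag_grid lags (seconds) scanned for the per-set optimum; positive
#'   lag means firing follows movement.
#' @param min_neighbors samples with fewer covered neighbors are undefined.
#' @param target_neighbors target median neighbor count for the d tuning.
#' @return object of class `parameter_space`.
#' @export
parameter_space <- function(channels, d = NULL, w = 1,
                            lag_grid = seq(-0.5, 0.5, by = 0.02),
                            min_neighbors = 10, target_neighbors = 200) {
  channels <- channel_set(channels)
  if (!length(channels)) stop("parameter_space: channels must be non-empty")
  if (!is.null(d) && d <= 0) stop("parameter_space: d must be > 0")
  if (w < 0) stop("parameter_space: w must be >= 0")
  structure(list(channels = channels, d = d, w = w, lag_grid = lag_grid,
                 min_neighbors = min_neighbors,
                 target_neighbors = target_neighbors),
            class = "parameter_space")
}

# z-scoring statistics from the reference set
space_scaling <- function(x) {
  list(center = colMeans(x), scale = apply(x, 2, sd))
}

apply_scaling <- function(x, sc) {
  s <- ifelse(sc$scale > 0, sc$scale, 1)
  sweep(sweep(x, 2, sc$center, "-"), 2, s, "/")
}

#' Tune the neighbor radius to a target median neighbor count
#'
#' Median distance to the k-th nearest neighbor over a probe subsample of
#' the reference set (exact, brute force).
#'
#' @param coords z-scored reference coordinates (n x k).
#' @param target_neighbors k.
#' @param n_probe probe subsample size.
#' @return radius d.
#' @export
tune_neighbor_radius <- function(coords, target_neighbors = 200,
                                 n_probe = 512) {
  n <- nrow(coords)
  probe <- if (n <= n_probe) seq_len(n)
           else round(seq(1, n, length.out = n_probe))
  dk <- cpp_kth_distance(coords, coords[probe, , drop = FALSE],
                         min(target_neighbors + 1L, n)) # +1: self included
  median(dk)
}

# shared driver around the C++ scan.  `reference`/`query` are lists with
# elements fr (full-grid rate), params (full-grid channel matrix), t.
nn_scan <- function(reference, query, space, offsets, same_recording,
                    ref_idx = NULL, query_idx = NULL, return_rho = FALSE) {
  ch <- space$channels
  missing_ch <- setdiff(ch, colnames(reference$params))
  if (length(missing_ch))
    stop("estimate_rate: channels absent from reference: ",
         paste(missing_ch, collapse = ", "))
  if (is.null(ref_idx)) ref_idx <- seq_along(reference$t)
  if (is.null(query_idx)) query_idx <- seq_along(query$t)
  refm <- reference$params[ref_idx, ch, drop = FALSE]
  sc <- space_scaling(refm)
  refz <- apply_scaling(refm, sc)
  qryz <- apply_scaling(query$params[query_idx, ch, drop = FALSE], sc)
  d <- space$d
  if (is.null(d)) d <- tune_neighbor_radius(refz, space$target_neighbors)
  res <- cpp_neighbor_scan(refz, reference$t[ref_idx], as.integer(ref_idx),
                           reference$fr, qryz, query$t[query_idx],
                           as.integer(query_idx), query$fr,
                           as.integer(offsets), d, space$w,
                           same_recording, space$min_neighbors, return_rho)
  res$d <- d
  res
}

#' Resampled firing-rate estimate
#'
#' Computes the model-free estimate `rho` on the query samples from the
#' reference recording, at one lag, together with its coverage and
#' firing-rate predictability R^2 (squared Pearson correlation between
#' `rho` and the query's instantaneous rate, over covered samples).
#'
#' @param unit a [unit_activity()] (query recording's unit).
#' @param params full-grid channel matrix of the query recording (from
#'   [inertial_channels()]).
#' @param t query time grid, seconds (uniform).
#' @param space a [parameter_space()].
#' @param lag lag in seconds (rate at `t + lag` paired with parameters at
#'   `t`).
#' @param reference optional list `(fr, params, t)` from another recording
#'   or block; defaults to the query recording itself (jackknife, with
#'   temporal exclusion).
#' @param ref_idx,query_idx optional index subsets into the respective grids.
#' @param same_recording set `FALSE` when `reference` is a different
#'   recording so the temporal exclusion window is not applied.
#' @return object of class `rate_estimate`: `rho` (NA where uncovered),
#'   `coverage`, `r2`, `lag`, `d`, `provenance`.
#' @export
estimate_rate <- function(unit, params, t, space, lag = 0, reference = NULL,
                          ref_idx = NULL, query_idx = NULL,
                          same_recording = is.null(reference)) {
  force(same_recording) # before `reference` is defaulted below
  fs <- 1 / (t[2] - t[1])
  query <- list(fr = unit$fr_instant, params = params, t = t)
  if (is.null(reference)) reference <- query
  off <- as.integer(round(lag * fs))
  res <- nn_scan(reference, query, space, off, same_recording,
                 ref_idx = ref_idx, query_idx = query_idx, return_rho = TRUE)
  cov <- res$coverage[1]
  if (cov == 0) warning("estimate_rate: zero coverage; estimate invalid")
  structure(list(rho = drop(res$rho), coverage = cov,
                 r2 = if (is.na(res$r[1])) NA_real_ else res$r[1]^2,
                 lag = lag, d = res$d,
                 provenance = if (same_recording) "self" else "cross"),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> lag %+.0f ms, d %.3f, coverage %.2f, R^2 %.3f (%s)\n",
              1000 * x$lag, x$d, x$coverage, x$r2, x$provenance))
  invisible(x)
}

#' Firing-rate predictability per inertial parameter set
#'
#' For each channel set, scans the lag grid and reports the best R^2 (with
#' its lag and coverage).  The conventional sets are angular velocity, raw
#' acceleration, its gravitational and non-gravitational components, and
#' combinations of angular velocity with each acceleration variant.
#'
#' @param unit a [unit_activity()].
#' @param params full-grid channel matrix (needs `ag_*`/`ang_*` columns for
#'   the gravitational sets; see [inertial_channels()]).
#' @param t time grid.
#' @param space a [parameter_space()] whose `channels` field is ignored in
#'   favor of `sets`.
#' @param sets named list of channel sets.
#' @param query_stride evaluate the estimate on every `query_stride`-th
#'   sample (the reference set stays complete); >1 trades a little R^2
#'   precision for speed on long recordings.
#' @return data.frame with columns `set`, `r2`, `lag`, `coverage`, `d`.
#' @export
predictability_table <- function(unit, params, t, space,
                                 sets = list(omega = "omega", acc = "acc",
                                             ag = "ag", ang = "ang",
                                             omega_acc = c("omega", "acc"),
                                             omega_ag = c("omega", "ag"),
                                             omega_ang = c("omega", "ang")),
                                 query_stride = 1L) {
  fs <- 1 / (t[2] - t[1])
  offsets <- as.integer(round(space$lag_grid * fs))
  rec <- list(fr = unit$fr_instant, params = params, t = t)
  qidx <- seq(1L, length(t), by = as.integer(query_stride))
  out <- lapply(names(sets), function(nm) {
    sp <- space
    sp$channels <- channel_set(sets[[nm]])
    res <- nn_scan(rec, rec, sp, offsets, TRUE, query_idx = qidx)
    r2 <- res$r^2
    if (all(is.na(r2))) {
      data.frame(set = nm, r2 = NA_real_, lag = NA_real_,
                 coverage = NA_real_, d = res$d)
    } else {
      best <- which.max(r2)
      data.frame(set = nm, r2 = r2[best], lag = space$lag_grid[best],
                 coverage = res$coverage[best], d = res$d)
    }
  })
  do.call(rbind, out)
}

#' Correlation between independent estimates from alternating blocks
#'
#' Partitions the recording into alternating blocks, builds two estimates
#' of the full rate series using only the odd-block and only the even-block
#' samples as references, and returns the Pearson correlation between them
#' on jointly covered samples.
#'
#' @param unit a [unit_activity()].
#' @param params,t full-grid channel matrix and time grid.
#' @param space a [parameter_space()].
#' @param block_length seconds.
#' @param lag lag in seconds.
#' @param query_stride evaluate on every `query_stride`-th sample.
#' @return list with `r`, `n` (jointly covered samples), `coverage_a`,
#'   `coverage_b`, `d`.
#' @export
independent_estimate_correlation <- function(unit, params, t, space,
                                             block_length = 30, lag = 0,
                                             query_stride = 1L) {
  span <- max(t) - min(t)
  if (span < 4 * block_length)
    stop("independent_estimate_correlation: need at least 4 blocks")
  fs <- 1 / (t[2] - t[1])
  off <- as.integer(round(lag * fs))
  block <- floor((t - min(t)) / block_length) %% 2
  ia <- which(block == 0)
  ib <- which(block == 1)
  qidx <- seq(1L, length(t), by = as.integer(query_stride))
  rec <- list(fr = unit$fr_instant, params = params, t = t)
  ea <- nn_scan(rec, rec, space, off, TRUE, ref_idx = ia, query_idx = qidx,
                return_rho = TRUE)
  eb <- nn_scan(rec, rec, space, off, TRUE, ref_idx = ib, query_idx = qidx,
                return_rho = TRUE)
  ra <- drop(ea$rho); rb <- drop(eb$rho)
  both <- is.finite(ra) & is.finite(rb)
  if (sum(both) < 10)
    return(list(r = NA_real_, n = sum(both), coverage_a = ea$coverage[1],
                coverage_b = eb$coverage[1], d = ea$d))
  list(r = cor(ra[both], rb[both]), n = sum(both),
       coverage_a = ea$coverage[1], coverage_b = eb$coverage[1], d = ea$d)
}

#' Null distribution of the independent-estimate correlation
#'
#' Each iteration circularly shifts the spike train by a uniform random
#' offset of at least `min_offset` seconds, recomputes the instantaneous
#' rate, and recomputes the independent-estimate correlation.
#'
#' @param spike_times the unit's spike times, seconds.
#' @param kin a [kinematic_series()] (grid and span).
#' @param params,space,block_length,lag as in
#'   [independent_estimate_correlation()].
#' @param n_iter iterations.
#' @param seed integer seed.
#' @param min_offset minimum circular offset, seconds.
#' @param query_stride evaluate on every `query_stride`-th sample.
#' @return object of class `null_distribution`: `r_values`, `n_iterations`,
#'   `seed`.
#' @export
shuffle_null <- function(spike_times, kin, params, space, n_iter = 10,
                         seed = 1L, block_length = 30, lag = 0,
                         min_offset = 10, query_stride = 1L) {
  t0 <- min(kin$t); t1 <- max(kin$t)
  if (t1 - t0 < 2 * min_offset)
    stop("shuffle_null: recording shorter than twice the minimum offset")
  set.seed(seed)
  r_values <- vapply(seq_len(n_iter), function(i) {
    offset <- runif(1, min_offset, (t1 - t0) - min_offset)
    sh <- circular_shift_spikes(spike_times, t0, t1, offset)
    u <- list(fr_instant = instantaneous_rate(sh, kin$t))
    independent_estimate_correlation(u, params, kin$t, space,
                                     block_length = block_length,
                                     lag = lag, query_stride = query_stride)$r
  }, numeric(1))
  structure(list(r_values = r_values, n_iterations = n_iter, seed = seed),
            class = "null_distribution")
}

#' Classify a unit's inertial selectivity
#'
#' A unit is rotation-selective (`omega_unit`) when its angular-velocity
#' predictability is at least `ratio` times the gravitational one and above
#' `floor`; symmetrically for `ag_unit`; otherwise `mixed`.
#'
#' @param r2_omega,r2_ag firing-rate predictability for the angular-velocity
#'   and gravitational parameter sets.
#' @param ratio fold-change criterion (default 8).
#' @param floor minimum predictability of the preferred parameter
#'   (default 0.1).
#' @return `"omega_unit"`, `"ag_unit"` or `"mixed"`.
#' @export
classify_inertial_selectivity <- function(r2_omega, r2_ag, ratio = 8,
                                          floor = 0.1) {
  stopifnot(is.finite(r2_omega), is.finite(r2_ag),
            r2_omega >= 0, r2_ag >= 0)
  if (r2_omega >= ratio * r2_ag && r2_omega > floor) "omega_unit"
  else if (r2_ag >= ratio * r2_omega && r2_ag > floor) "ag_unit"
  else "mixed"
}
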
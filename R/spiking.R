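# Spike-train statistics: instantaneous firing rate on the kinematic grid,
# ISI regularity, and discharge-based unit classification.

#' Instantaneous firing rate on a time grid
#'
#' The rate at each timestamp is the reciprocal of the inter-spike interval
#' enclosing it; before the first and after the last spike the rate is 0.
#' This definition preserves the sharp rate fluctuations of irregular trains
#' that kernel smoothing would blur.  A Gaussian-kernel alternative is
#' available via `kernel_sd`.
#'
#' @param spike_times numeric vector, seconds, strictly increasing.
#' @param timestamps evaluation grid, seconds.
#' @param kernel_sd if non-`NULL`, instead return a Gaussian-kernel rate
#'   with this SD (seconds).
#' @return numeric rate series, Hz, on `timestamps`.
#' @export
instantaneous_rate <- function(spike_times, timestamps, kernel_sd = NULL) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times, strictly = TRUE))
    stop("instantaneous_rate: spike_times must be strictly increasing")
  if (length(spike_times) < 2) {
    warning("instantaneous_rate: fewer than 2 spikes; returning zeros")
    return(numeric(length(timestamps)))
  }
  if (!is.null(kernel_sd)) {
    out <- numeric(length(timestamps))
    for (s in spike_times)
      out <- out + exp(-0.5 * ((timestamps - s) / kernel_sd)^2)
    return(out / (kernel_sd * sqrt(2 * pi)))
  }
  isi <- diff(spike_times)
  idx <- findInterval(timestamps, spike_times)
  inside <- idx >= 1 & idx < length(spike_times)
  out <- numeric(length(timestamps))
  out[inside] <- 1 / isi[idx[inside]]
  out
}

#' Detect immobility epochs from angular speed
#'
#' Contiguous runs with `||omega|| < speed_threshold` lasting at least
#' `min_duration`.
#'
#' @param kin a [kinematic_series()].
#' @param speed_threshold deg/s (default 15, the conventional speed floor).
#' @param min_duration seconds.
#' @return two-column matrix of epoch `start`/`end` times (possibly 0 rows).
#' @export
immobility_epochs <- function(kin, speed_threshold = 15, min_duration = 1) {
  speed <- sqrt(rowSums(kin$omega^2))
  still <- speed < speed_threshold
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths >= min_duration * kin$sample_rate)
  cbind(start = kin$t[starts[keep]], end = kin$t[ends[keep]])
}

#' ISI coefficient of variation and log-ISI entropy
#'
#' CV is SD/mean of inter-spike intervals, optionally restricted to ISIs
#' falling entirely inside the supplied epochs (e.g. immobility).  Entropy
#' is the Shannon entropy (bits) of the log2-ISI histogram with 0.02
#' log2-unit bins over \[1 ms, 10 s\].
#'
#' @param spike_times numeric vector, seconds.
#' @param epochs optional two-column matrix of `start`/`end` times.
#' @return list with `cv`, `entropy`, `n_isi`, `mean_rate` (Hz, over the
#'   span of the train).
#' @export
isi_statistics <- function(spike_times, epochs = NULL) {
  spike_times <- as.numeric(spike_times)
  n <- length(spike_times)
  if (n < 2) return(list(cv = NA_real_, entropy = NA_real_, n_isi = 0L,
                         mean_rate = NA_real_))
  isi <- diff(spike_times)
  if (!is.null(epochs) && nrow(epochs) > 0) {
    keep <- rep(FALSE, length(isi))
    for (e in seq_len(nrow(epochs)))
      keep <- keep | (spike_times[-n] >= epochs[e, 1] &
                      spike_times[-1] <= epochs[e, 2])
    isi <- isi[keep]
  } else if (!is.null(epochs)) {
    warning("isi_statistics: empty epochs; statistics undefined")
    return(list(cv = NA_real_, entropy = NA_real_, n_isi = 0L,
                mean_rate = n / diff(range(spike_times))))
  }
  if (length(isi) < 2) return(list(cv = NA_real_, entropy = NA_real_,
                                   n_isi = length(isi),
                                   mean_rate = n / diff(range(spike_times))))
  if (length(isi) < 50)
    warning("isi_statistics: fewer than 50 ISIs; estimates unstable")
  cv <- sd(isi) / mean(isi)
  edges <- seq(log2(0.001), log2(10), by = 0.02)
  l2 <- log2(pmin(pmax(isi, 0.001), 10 - 1e-9))
  counts <- tabulate(findInterval(l2, edges), nbins = length(edges))
  p <- counts[counts > 0] / sum(counts)
  list(cv = cv, entropy = -sum(p * log2(p)), n_isi = length(isi),
       mean_rate = n / diff(range(spike_times)))
}

#' Classify a unit from its firing rate and ISI entropy
#'
#' Low log-ISI entropy (< 6.3 bits) marks putative mossy fibers; otherwise a
#' low mean rate (< 12 Hz) marks putative Golgi cells; the remainder are
#' putative Purkinje cells.  Values at exactly the threshold pass it (an
#' entropy of exactly 6.3 is not a mossy fiber).
#'
#' @param mean_rate Hz.
#' @param entropy bits.
#' @param entropy_cutoff,rate_cutoff decision thresholds.
#' @return character label: `"putative_mossy_fiber"`, `"putative_golgi"` or
#'   `"putative_purkinje"`.
#' @export
classify_unit <- function(mean_rate, entropy, entropy_cutoff = 6.3,
                          rate_cutoff = 12) {
  stopifnot(is.finite(mean_rate), is.finite(entropy))
  if (entropy < entropy_cutoff) "putative_mossy_fiber"
  else if (mean_rate < rate_cutoff) "putative_golgi"
  else "putative_purkinje"
}

#' Bundle a spike train with its derived statistics
#'
#' @param spike_times numeric vector, seconds.
#' @param kin a [kinematic_series()] providing the rate grid.
#' @param immobility optional epochs for the CV computation; computed from
#'   `kin` when `NULL`.
#' @return object of class `unit_activity`: `spike_times`, `fr_instant`,
#'   `mean_rate`, `isi_cv` (immobility-restricted when possible), `entropy`,
#'   `label`.
#' @export
unit_activity <- function(spike_times, kin, immobility = NULL) {
  fr <- instantaneous_rate(spike_times, kin$t)
  if (is.null(immobility)) immobility <- immobility_epochs(kin)
  stats_all <- isi_statistics(spike_times)
  cv <- if (nrow(immobility) > 0) {
    s <- suppressWarnings(isi_statistics(spike_times, immobility))
    if (is.finite(s$cv)) s$cv else stats_all$cv
  } else stats_all$cv
  label <- if (is.finite(stats_all$mean_rate) && is.finite(stats_all$entropy))
    classify_unit(stats_all$mean_rate, stats_all$entropy) else NA_character_
  structure(list(spike_times = spike_times, fr_instant = fr,
                 mean_rate = stats_all$mean_rate, isi_cv = cv,
                 entropy = stats_all$entropy, label = label, t = kin$t),
            class = "unit_activity")
}

#' @export
print.unit_activity <- function(x, ...) {
  cat(sprintf("<unit_activity> %d spikes, mean %.1f Hz, ISI CV %.2f, entropy %.2f bits (%s)\n",
              length(x$spike_times), x$mean_rate, x$isi_cv, x$entropy,
              x$label))
  invisible(x)
}

# circular shift of a spike train within the recording span [t0, t1]
circular_shift_spikes <- function(spike_times, t0, t1, offset) {
  span <- t1 - t0
  sort(((spike_times - t0 + offset) %% span) + t0)
}
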
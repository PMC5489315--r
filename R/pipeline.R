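# End-to-end orchestration: session -> per-unit report bundle.

#' Analysis configuration
#'
#' Gathers every tunable of the pipeline with its default.  A run's merged
#' config is embedded in its outputs.
#'
#' @param correction_gain complementary-filter gain per sample.
#' @param d neighbor radius (`NULL`: tuned to `target_neighbors`).
#' @param w temporal exclusion half-window, s.
#' @param lag_grid lags scanned, s.
#' @param min_neighbors,target_neighbors neighbor-count rules.
#' @param block_length alternating-block length, s.
#' @param n_null_iterations shuffle iterations of the estimator null.
#' @param n_shuffles shuffle iterations for tuning significance bands.
#' @param grid_n,cap_radius tilt-sphere grid size and cap radius (deg).
#' @param min_occupancy minimum samples per tilt cap.
#' @param hemifield_threshold g, for the stability index.
#' @param frame_band,frame_cutoff reference-frame decision band (deg) and
#'   `Delta S` cutoff.
#' @param sets named list of channel sets for the predictability table.
#' @param global_sets list of regressor sets for the global linear models.
#' @param stages character vector of stages to run (subset of
#'   `"predictability"`, `"tuning"`, `"tiltmap"`, `"stability"`,
#'   `"frames"`, `"models"`, `"null"`).
#' @param seed master seed.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(correction_gain = 0.01, d = NULL, w = 1,
                            lag_grid = seq(-0.5, 0.5, by = 0.02),
                            min_neighbors = 10, target_neighbors = 200,
                            block_length = 30, n_null_iterations = 10,
                            n_shuffles = 100, grid_n = 642, cap_radius = 20,
                            min_occupancy = 500,
                            hemifield_threshold = 0.25,
                            frame_band = c(80, 100), frame_cutoff = 0.5,
                            sets = list(omega = "omega", ag = "ag",
                                        omega_ag = c("omega", "ag")),
                            global_sets = list(c("omega"),
                                               c("omega", "omega_dot", "ag")),
                            stages = c("predictability", "tuning", "tiltmap",
                                       "stability", "frames", "models",
                                       "null"),
                            seed = 1L) {
  structure(as.list(environment()), class = "analysis_config")
}

analyze_one_unit <- function(id, spikes, kin, orient, channels, deriv,
                             config) {
  out <- list(unit_id = id, n_spikes = length(spikes))
  ua <- unit_activity(spikes, kin)
  out$mean_rate <- ua$mean_rate
  out$isi_cv <- ua$isi_cv
  out$entropy <- ua$entropy
  out$label <- ua$label
  fs <- kin$sample_rate
  space <- parameter_space("omega", d = config$d, w = config$w,
                           lag_grid = config$lag_grid,
                           min_neighbors = config$min_neighbors,
                           target_neighbors = config$target_neighbors)
  if ("predictability" %in% config$stages) {
    pt <- predictability_table(ua, channels, kin$t, space,
                               sets = config$sets)
    out$predictability <- pt
    r2o <- pt$r2[pt$set == "omega"]
    r2g <- pt$r2[pt$set == "ag"]
    if (length(r2o) && length(r2g) && is.finite(r2o) && is.finite(r2g))
      out$selectivity <- classify_inertial_selectivity(r2o, r2g)
  }
  if ("tuning" %in% config$stages) {
    glc <- gain_lag_curve(ua$fr_instant, kin$omega, fs,
                          lag_grid = config$lag_grid,
                          n_shuffles = config$n_shuffles,
                          seed = config$seed)
    out$gain <- glc$optimal$gain
    out$optimal_lag <- glc$optimal_lag
    out$sensitivity <- glc$optimal$components
    out$sensitivity_significant <- glc$significant
  }
  grid <- sphere_grid(config$grid_n, config$cap_radius)
  if ("tiltmap" %in% config$stages) {
    map <- tryCatch(tilt_rate_map(ua$fr_instant, orient$gravity_head, grid,
                                  config$min_occupancy),
                    error = function(e) NULL)
    out$tilt_map_cv <- if (is.null(map)) NA_real_ else map$cv
  }
  if ("stability" %in% config$stages) {
    out$sigma_x <- stability_index(ua$fr_instant, kin$omega,
                                   orient$gravity_head, "x", fs,
                                   threshold = config$hemifield_threshold)$sigma
    out$sigma_y <- stability_index(ua$fr_instant, kin$omega,
                                   orient$gravity_head, "y", fs,
                                   threshold = config$hemifield_threshold)$sigma
  }
  if ("frames" %in% config$stages) {
    lag0 <- if (!is.null(out$optimal_lag)) out$optimal_lag else 0
    field <- local_sensitivity_field(ua$fr_instant, kin$omega,
                                     deriv$omega_earth,
                                     orient$gravity_head, grid,
                                     lag = lag0, sample_rate = fs,
                                     min_occupancy = config$min_occupancy,
                                     n_shuffles = min(config$n_shuffles, 50),
                                     seed = config$seed)
    fc <- tryCatch({
      pi_ <- collinearity_profile(field, "internal")
      pe_ <- collinearity_profile(field, "external")
      classify_reference_frame(pi_, pe_, band = config$frame_band,
                               cutoff = config$frame_cutoff)
    }, error = function(e) list(label = "unclassified", delta_s = NA_real_,
                                reason = conditionMessage(e)))
    out$frame_label <- fc$label
    out$delta_s <- fc$delta_s
    out$field_occupied <- sum(is.finite(field$gain_internal))
    if ("models" %in% config$stages) {
      loc <- tryCatch(local_linear_r2(field, ua$fr_instant, kin$omega,
                                      orient$gravity_head, fs),
                      error = function(e) list(r2 = NA_real_))
      out$r2_local <- loc$r2
    }
  }
  if ("models" %in% config$stages) {
    regressors <- list(omega = kin$omega, omega_dot = deriv$omega_dot,
                       ag = orient$gravity_head,
                       ag_dot = deriv$gravity_jerk)
    lag0 <- if (!is.null(out$optimal_lag)) out$optimal_lag else 0
    out$r2_global <- lapply(config$global_sets, function(s)
      list(set = paste(s, collapse = "+"),
           r2 = global_linear_fit(ua$fr_instant, regressors, s, lag0,
                                  fs)$r2))
  }
  span <- max(kin$t) - min(kin$t)
  if ("null" %in% config$stages && span >= 4 * config$block_length &&
      span >= 20) {
    ind <- independent_estimate_correlation(ua, channels, kin$t, space,
                                            block_length = config$block_length)
    out$independent_r <- ind$r
    nd <- shuffle_null(spikes, kin, channels, space,
                       n_iter = config$n_null_iterations,
                       seed = config$seed,
                       block_length = config$block_length)
    out$null_mean <- mean(nd$r_values, na.rm = TRUE)
    out$null_sd <- sd(nd$r_values, na.rm = TRUE)
  } else if ("null" %in% config$stages) {
    message(sprintf(
      "run_analysis: unit %s: recording too short for the %g s block null; skipped",
      id, config$block_length))
  }
  out
}

#' Run the full analysis on a session
#'
#' Executes orientation estimation, spiking statistics and the configured
#' analysis stages for every unit.  A failing stage isolates the unit (the
#' failure is logged in the report) and the pipeline continues.  Identical
#' seeds give identical outputs.
#'
#' @param session a [load_session()] result (or a list with `kin` and
#'   `units`).
#' @param config an [analysis_config()].
#' @param out_dir optional directory; per-unit JSON files and a summary TSV
#'   are written there, with the config embedded.
#' @return object of class `analysis_report`: `units` (per-unit result
#'   lists), `failures` (named character vector), `config`.
#' @export
run_analysis <- function(session, config = analysis_config(),
                         out_dir = NULL) {
  kin <- session$kin
  orient <- estimate_orientation(kin, config$correction_gain)
  channels <- inertial_channels(kin, orient)
  deriv <- kinematic_derivatives(kin, orient)
  results <- list()
  failures <- character(0)
  for (id in names(session$units)) {
    res <- tryCatch(
      analyze_one_unit(id, session$units[[id]], kin, orient, channels,
                       deriv, config),
      error = function(e) {
        structure(conditionMessage(e), class = "unit_failure")
      })
    if (inherits(res, "unit_failure")) {
      failures[id] <- unclass(res)
      message(sprintf("run_analysis: unit %s failed: %s", id, res))
    } else {
      results[[id]] <- res
    }
  }
  report <- structure(list(units = results, failures = failures,
                           config = config),
                      class = "analysis_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(results)) {
      payload <- results[[id]]
      payload$config <- unclass(config)
      jsonlite::write_json(payload,
                           file.path(out_dir, paste0(id, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows", null = "null")
    }
    summ <- report_summary(report)
    data.table::fwrite(summ, file.path(out_dir, "summary.tsv"), sep = "\t")
  }
  report
}

#' Flatten an analysis report into a per-unit summary table
#' @param report an `analysis_report`.
#' @return data.frame, one row per analyzed unit.
#' @export
report_summary <- function(report) {
  if (!length(report$units)) return(data.frame(unit_id = character(0)))
  rows <- lapply(report$units, function(u) {
    data.frame(unit_id = u$unit_id, n_spikes = u$n_spikes,
               mean_rate = u$mean_rate, isi_cv = u$isi_cv,
               entropy = u$entropy, label = u$label,
               selectivity = u$selectivity %||% NA_character_,
               gain = u$gain %||% NA_real_,
               optimal_lag = u$optimal_lag %||% NA_real_,
               tilt_map_cv = u$tilt_map_cv %||% NA_real_,
               sigma_x = u$sigma_x %||% NA_real_,
               sigma_y = u$sigma_y %||% NA_real_,
               frame_label = u$frame_label %||% NA_character_,
               delta_s = u$delta_s %||% NA_real_,
               independent_r = u$independent_r %||% NA_real_,
               null_mean = u$null_mean %||% NA_real_)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d units analyzed, %d failed\n",
              length(x$units), length(x$failures)))
  invisible(x)
}
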
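# Plain-text session I/O.  All numeric values are written as %.17g so that
# files round-trip bit-exactly through the readers.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a kinematic series as TSV
#'
#' Columns `t omega_x omega_y omega_z acc_x acc_y acc_z` (s, deg/s, g).
#'
#' @param kin a [kinematic_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kinematics <- function(kin, path) {
  m <- cbind(kin$t, kin$omega, kin$acc)
  lines <- c(paste(c("t", colnames(kin$omega), colnames(kin$acc)),
                   collapse = "\t"),
             apply(matrix(fmt_num(m), nrow(m)), 1, paste, collapse = "\t"))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("write_kinematics: cannot write ", path)
  invisible(path)
}

#' Read a kinematic series from TSV
#' @param path file written by [write_kinematics()] (or any TSV with the
#'   same header).
#' @return a [kinematic_series()].
#' @export
read_kinematics <- function(path) {
  if (!file.exists(path)) stop("read_kinematics: no such file: ", path)
  d <- data.table::fread(path, sep = "\t")
  need <- c("t", "omega_x", "omega_y", "omega_z", "acc_x", "acc_y", "acc_z")
  if (!all(need %in% names(d)))
    stop("read_kinematics: missing columns in ", path)
  kinematic_series(d$t, as.matrix(d[, c("omega_x", "omega_y", "omega_z")]),
                   as.matrix(d[, c("acc_x", "acc_y", "acc_z")]))
}

#' Write spike times, one per line
#' @param spike_times seconds.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spike_times, path) {
  writeLines(fmt_num(spike_times), path)
  invisible(path)
}

#' Read spike times (one float per line)
#' @param path input file.
#' @return numeric vector, seconds.
#' @export
read_spikes <- function(path) {
  if (!file.exists(path)) stop("read_spikes: no such file: ", path)
  as.numeric(readLines(path))
}

#' Write generator ground truth as TSV
#'
#' Columns: time, true quaternion (scalar-first `q_w q_x q_y q_z`), true
#' gravity direction and true (noiseless) angular velocity.
#'
#' @param truth `ground_truth` from [simulate_head_kinematics()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  m <- cbind(truth$t, truth$q, truth$gravity_head, truth$omega)
  hdr <- c("t", "q_w", "q_x", "q_y", "q_z", "ag_x", "ag_y", "ag_z",
           "omega_x", "omega_y", "omega_z")
  lines <- c(paste(hdr, collapse = "\t"),
             apply(matrix(fmt_num(m), nrow(m)), 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read generator ground truth
#' @param path file written by [write_ground_truth()].
#' @return `ground_truth`-like list (`t`, `q`, `gravity_head`, `omega`).
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("read_ground_truth: no such file: ", path)
  d <- data.table::fread(path, sep = "\t")
  structure(list(t = d$t,
                 q = as.matrix(d[, c("q_w", "q_x", "q_y", "q_z")]),
                 gravity_head = as.matrix(d[, c("ag_x", "ag_y", "ag_z")]),
                 omega = as.matrix(d[, c("omega_x", "omega_y", "omega_z")])),
            class = "ground_truth")
}

#' Write a complete synthetic session to disk
#'
#' Simulates kinematics and every unit, then writes the kinematics TSV,
#' per-unit spike files, the ground-truth TSV and a YAML manifest listing
#' them all.  Identical seeds give byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param specs named list of [tuning_spec()]s (names become unit ids).
#' @param out_dir writable directory (created if needed).
#' @param blocks optional data.frame with columns `label`, `start`, `end`
#'   (seconds); default one `dark_active` block covering the session.
#' @return path to the manifest, invisibly; the manifest itself carries the
#'   file names and each unit's tuning kind and parameters.
#' @export
build_session_fixture <- function(config, specs, out_dir, blocks = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("build_session_fixture: cannot create directory ", out_dir)
  sim <- simulate_head_kinematics(config)
  write_kinematics(sim$kin, file.path(out_dir, "kinematics.tsv"))
  write_ground_truth(sim$truth, file.path(out_dir, "ground_truth.tsv"))
  if (is.null(names(specs)))
    names(specs) <- sprintf("unit_%02d", seq_along(specs))
  units <- list()
  for (i in seq_along(specs)) {
    id <- names(specs)[i]
    sp <- specs[[i]]
    spikes <- simulate_unit(sim$kin, sim$truth, sp,
                            seed = (config$seed %% 100000L) * 100L + i)
    f <- paste0(id, ".spikes.txt")
    write_spikes(spikes, file.path(out_dir, f))
    units[[id]] <- list(id = id, file = f, kind = sp$kind,
                        baseline_rate = sp$baseline_rate, gain = sp$gain,
                        preferred_axis = as.numeric(sp$preferred_axis),
                        preferred_tilt = as.numeric(sp$preferred_tilt),
                        response_lag = sp$response_lag, isi_cv = sp$isi_cv,
                        n_spikes = length(spikes))
  }
  if (is.null(blocks))
    blocks <- data.frame(label = "dark_active", start = 0,
                         end = config$duration)
  manifest <- list(
    session = list(sample_rate = config$sample_rate,
                   duration = config$duration, seed = config$seed),
    files = list(kinematics = "kinematics.tsv",
                 ground_truth = "ground_truth.tsv"),
    blocks = lapply(seq_len(nrow(blocks)), function(b)
      list(label = blocks$label[b], start = blocks$start[b],
           end = blocks$end[b])),
    units = unname(units))
  mpath <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Load and validate a session from its manifest
#'
#' Reads the manifest, the kinematics, every unit's spike file and the
#' ground truth when present.  Validation failures are collected in a
#' report; missing files, non-uniform timestamps, overlapping blocks and a
#' sample-rate mismatch are fatal, low-spike units are warnings.
#'
#' @param manifest_path path to a YAML manifest.
#' @param expected_sample_rate if non-`NULL`, a differing kinematics rate is
#'   fatal (no implicit resampling).
#' @param min_spikes units below this count trigger a warning.
#' @return object of class `session`: `kin`, `units` (named list of spike
#'   vectors), `truth` (or `NULL`), `blocks`, `manifest`, `report`
#'   (`warnings` character vector).
#' @export
load_session <- function(manifest_path, expected_sample_rate = NULL,
                         min_spikes = 100) {
  if (!file.exists(manifest_path))
    stop("load_session: no such manifest: ", manifest_path)
  manifest <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  warnings <- character(0)
  kin <- read_kinematics(file.path(base, manifest$files$kinematics))
  if (!is.null(expected_sample_rate) &&
      abs(kin$sample_rate - expected_sample_rate) >
        1e-3 * expected_sample_rate) {
    warning(sprintf("load_session: kinematics at %.6g Hz but %.6g Hz required",
                    kin$sample_rate, expected_sample_rate))
    stop("load_session: sample-rate mismatch (resampling is off by default)")
  }
  blocks <- do.call(rbind, lapply(manifest$blocks, function(b)
    data.frame(label = b$label, start = b$start, end = b$end)))
  if (!is.null(blocks) && nrow(blocks) > 1) {
    o <- order(blocks$start)
    b <- blocks[o, ]
    if (any(b$end[-nrow(b)] > b$start[-1] + 1e-9))
      stop("load_session: overlapping blocks in manifest")
  }
  if (!is.null(blocks)) {
    if (any(blocks$start < min(kin$t) - 1e-6) ||
        any(blocks$end > max(kin$t) + 1 / kin$sample_rate + 1e-6))
      stop("load_session: block outside the recording span")
  }
  units <- list()
  for (u in manifest$units) {
    sp <- read_spikes(file.path(base, u$file))
    if (length(sp) < min_spikes)
      warnings <- c(warnings,
                    sprintf("unit %s has only %d spikes", u$id, length(sp)))
    units[[u$id]] <- sp
  }
  truth <- NULL
  if (!is.null(manifest$files$ground_truth)) {
    gt <- file.path(base, manifest$files$ground_truth)
    if (file.exists(gt)) truth <- read_ground_truth(gt)
  }
  structure(list(kin = kin, units = units, truth = truth, blocks = blocks,
                 manifest = manifest, report = list(warnings = warnings)),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> %.0f s @ %.6g Hz, %d units, %d block(s), %d warning(s)\n",
              diff(range(x$kin$t)), x$kin$sample_rate, length(x$units),
              if (is.null(x$blocks)) 0L else nrow(x$blocks),
              length(x$report$warnings)))
  invisible(x)
}
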
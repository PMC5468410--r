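#' Write / read a recording as plain-text CSV with a JSON sidecar
#'
#' The signal is stored wide (one column per channel, one row per sample) in
#' `<path>.csv`, metadata (sampling rate, channel order) in `<path>.json`,
#' and annotations -- if present -- in `<path>_annotations.csv` with columns
#' `onset_s`, `duration_s`, `condition`.
#'
#' @param rec An [eeg_recording()].
#' @param path Path stem (no extension).
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an [eeg_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  sig <- tibble::as_tibble(t(rec$data), .name_repair = "minimal")
  names(sig) <- rec$channels
  readr::write_csv(sig, paste0(path, ".csv"))
  jsonlite::write_json(
    list(fs = rec$fs, channels = rec$channels,
         n_samples = ncol(rec$data)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(rec$annotations)) {
    ann <- rec$annotations
    readr::write_csv(
      tibble::tibble(onset_s = ann$onset, duration_s = ann$duration,
                     condition = ann$condition),
      paste0(path, "_annotations.csv"))
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sig <- readr::read_csv(paste0(path, ".csv"), show_col_types = FALSE)
  ann_path <- paste0(path, "_annotations.csv")
  ann <- NULL
  if (file.exists(ann_path)) {
    raw <- readr::read_csv(ann_path, show_col_types = FALSE)
    ann <- tibble::tibble(onset = raw$onset_s, duration = raw$duration_s,
                          condition = raw$condition)
  }
  m <- t(as.matrix(sig[, meta$channels]))
  dimnames(m) <- NULL
  eeg_recording(m, meta$fs, meta$channels, ann)
}

#' Serialize / restore a course configuration as YAML
#'
#' @param config A [sim_course_config()].
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   [sim_course_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_course_config"))
  out <- unclass(config)
  out$perf_curve <- as.list(out$perf_curve)   # keep names through YAML
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_course_config(
    n_sessions = raw$n_sessions, channels = raw$channels, fs = raw$fs,
    condition_block_duration = raw$condition_block_duration,
    blocks_per_session = raw$blocks_per_session, iaf_true = raw$iaf_true,
    theta_effect = raw$theta_effect, alpha_effect = raw$alpha_effect,
    drift_schedule = raw$drift_schedule,
    perf_curve = unlist(raw$perf_curve),
    noise_sd = raw$noise_sd, theta_amplitude = raw$theta_amplitude,
    alpha_amplitude = raw$alpha_amplitude, behavior_sd = raw$behavior_sd,
    seed = raw$seed)
}

#' Write course results as CSVs plus a JSON manifest
#'
#' One directory per run: `pairs.csv` (session-pair metrics), `sessions.csv`,
#' `folds.csv` (fold-level AUCs) and `manifest.json` recording the package
#' version, seed, configuration and its hash, so a run can be reproduced
#' exactly.
#'
#' @param course A `training_course` from [run_course()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_course <- function(course, dir) {
  stopifnot(inherits(course, "training_course"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(course$pairs, file.path(dir, "pairs.csv"))
  readr::write_csv(course$sessions, file.path(dir, "sessions.csv"))
  readr::write_csv(course$folds, file.path(dir, "folds.csv"))
  jsonlite::write_json(
    list(package = "neurotrain",
         version = as.character(utils::packageVersion("neurotrain")),
         seed = course$seed,
         iaf = course$iaf$iaf,
         performance_reference = course$performance_reference,
         config = unclass(course$config),
         config_hash = rlang::hash(unclass(course$config))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
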
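#' @title Pipeline orchestration and retention policy
#' @description Configuration, end-to-end pipeline runs with a
#'   reproducibility manifest, and the recording retention purge (raw
#'   recordings are privacy-sensitive and deleted after a configurable
#'   number of hours; derived, non-identifiable event logs and statistics
#'   are never purged).
#' @name app
NULL

#' Pipeline run configuration
#'
#' @param zone_config path to a zone configuration JSON
#'   ([write_zone_config()]).
#' @param tracker a [tracker_config()].
#' @param events an [event_config()].
#' @param retention_hours hours raw recordings are kept before
#'   [purge_expired()] removes them; must be positive (default 48).
#' @param seed integer seed echoed into the run manifest.
#' @param output_dir directory for event logs, statistics and the
#'   manifest.
#' @return a list of class `run_config`.
#' @export
run_config <- function(zone_config, tracker = tracker_config(),
                       events = event_config(), retention_hours = 48,
                       seed = 1, output_dir = ".") {
  if (!is.numeric(retention_hours) || retention_hours <= 0) {
    stop("retention_hours must be positive")
  }
  if (!file.exists(zone_config)) {
    stop("zone config not found: ", zone_config)
  }
  structure(list(zone_config = zone_config, tracker = tracker,
                 events = events, retention_hours = as.double(retention_hours),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Run the monitoring pipeline on a recorded stream
#'
#' Reads the zone configuration and the detection stream, counts confirmed
#' entries, writes the event log CSV, and — when a gold observation log is
#' supplied — classifies observations, computes sensitivity/specificity
#' with confidence intervals and writes them as JSON. Every stage's
#' parameters, the seed, the package version and input checksums are
#' echoed into a run-manifest JSON so a run can be reproduced exactly.
#' The input stream file is never modified.
#'
#' @param config a [run_config()].
#' @param stream_path JSON-lines detection stream.
#' @param gold_path optional gold observation-log CSV
#'   ([read_gold_log()]).
#' @param legacy run the engine in legacy (pre-fix) mode.
#' @return named character vector of output paths (`events`, `manifest`,
#'   and `stats` when gold was supplied).
#' @export
run_pipeline <- function(config, stream_path, gold_path = NULL,
                         legacy = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(stream_path)) stop("stream file not found: ", stream_path)
  if (!is.null(gold_path) && !file.exists(gold_path)) {
    stop("gold log not found: ", gold_path)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  zc <- read_zone_config(config$zone_config)
  stream <- read_stream(stream_path)
  events <- count_entries(stream, zc$zone, tracker_cfg = config$tracker,
                          event_cfg = config$events,
                          min_confidence = zc$min_confidence,
                          legacy = legacy)
  paths <- c(events = file.path(config$output_dir, "events.csv"),
             manifest = file.path(config$output_dir, "run_manifest.json"))
  write_event_log(events, paths[["events"]])
  if (!is.null(gold_path)) {
    obs <- classify_observations(events, read_gold_log(gold_path))
    stats <- diagnostic_stats(confusion(obs))
    paths <- c(paths, stats = file.path(config$output_dir, "stats.json"))
    jsonlite::write_json(
      list(sensitivity = stats$sensitivity, specificity = stats$specificity,
           sens_ci = unname(stats$sens_ci), spec_ci = unname(stats$spec_ci),
           n_pos = stats$n_pos, n_neg = stats$n_neg,
           ci_method = stats$ci_method),
      paths[["stats"]], auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("zonewatch")),
    seed = config$seed,
    zone_config = config$zone_config,
    stream_path = stream_path,
    gold_path = gold_path,
    legacy = legacy,
    tracker = unclass(config$tracker),
    events = unclass(config$events),
    retention_hours = config$retention_hours,
    input_md5 = as.list(tools::md5sum(c(config$zone_config, stream_path))))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  paths
}

#' Register a recording for retention tracking
#'
#' Writes a sidecar manifest (`<file>.manifest.json`) recording when the
#' file was created. Filesystem timestamps are unreliable across copies,
#' so the purge relies on these sidecars: only files with a sidecar are
#' ever deleted, which automatically protects derived event logs and
#' statistics.
#'
#' @param path recording file.
#' @param created POSIXct creation time (defaults to now).
#' @export
register_recording <- function(path, created = Sys.time()) {
  stopifnot(file.exists(path))
  jsonlite::write_json(
    list(path = basename(path),
         created = format(created, "%Y-%m-%dT%H:%M:%S%z")),
    paste0(path, ".manifest.json"), auto_unbox = TRUE)
  invisible(paste0(path, ".manifest.json"))
}

#' Delete recordings older than the retention window
#'
#' Scans `recordings_dir` for sidecar manifests written by
#' [register_recording()] and deletes exactly those recordings whose
#' recorded creation time is more than `retention_hours` before `now`
#' (together with their sidecars). Files without a sidecar — event logs,
#' statistics, anything derived and non-identifiable — are never touched.
#' Idempotent: an immediate second invocation deletes nothing. An
#' undeletable file is reported and skipped; the purge continues and the
#' result carries a nonzero `exit_status` attribute.
#'
#' @param recordings_dir directory to scan (recursively).
#' @param retention_hours retention window in hours (default 48).
#' @param now POSIXct reference time, injectable for testing.
#' @return character vector of deleted recording paths, with attribute
#'   `exit_status` (0 on full success).
#' @export
purge_expired <- function(recordings_dir, retention_hours = 48,
                          now = Sys.time()) {
  stopifnot(dir.exists(recordings_dir), retention_hours > 0)
  manifests <- list.files(recordings_dir, pattern = "\\.manifest\\.json$",
                          recursive = TRUE, full.names = TRUE)
  deleted <- character(0)
  status <- 0L
  for (m in manifests) {
    info <- tryCatch(jsonlite::fromJSON(m), error = function(e) NULL)
    if (is.null(info) || is.null(info$created)) next
    created <- as.POSIXct(info$created, format = "%Y-%m-%dT%H:%M:%S%z")
    if (is.na(created)) next
    age_h <- as.double(difftime(now, created, units = "hours"))
    if (age_h <= retention_hours) next
    target <- sub("\\.manifest\\.json$", "", m)
    if (file.exists(target)) {
      ok <- suppressWarnings(file.remove(target))
      if (!ok) {
        warning("could not delete expired recording: ", target)
        status <- 1L
        next
      }
      deleted <- c(deleted, target)
    }
    suppressWarnings(file.remove(m))
  }
  structure(deleted, exit_status = status)
}
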
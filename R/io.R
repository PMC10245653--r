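# File plumbing. All tables are plain CSV with a '#'-prefixed provenance
# header (config hash, seed, package version — no timestamps, so reruns
# are byte-identical). Units: seconds, cm, Hz; frames 0-based in files.

provenance_header <- function(seed = NA, extra = character()) {
  c(sprintf("# astroca %s", as.character(utils::packageVersion("astroca"))),
    sprintf("# seed: %s", seed),
    if (length(extra)) paste0("# ", extra))
}

write_csv_prov <- function(df, path, seed = NA, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, extra), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_prov <- function(path, required = NULL) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    stop_if(length(miss) > 0,
            sprintf("%s: missing required column(s): %s",
                    basename(path), paste(miss, collapse = ", ")))
  }
  df
}

#' Write / read fluorescence trace tables
#'
#' CSV layout: a `time` column (seconds) followed by one column per cell.
#'
#' @param traces frames x cells numeric matrix.
#' @param fs sampling rate, Hz.
#' @param path file path.
#' @param seed seed recorded in the provenance header.
#' @return `write_traces_csv` the path, invisibly; `read_traces_csv` a
#'   list with `traces` (matrix), `time`, `fs` (estimated from the time
#'   column).
#' @export
write_traces_csv <- function(traces, fs, path, seed = NA) {
  time <- (seq_len(nrow(traces)) - 1) / fs
  df <- data.frame(time = time, traces, check.names = FALSE)
  write_csv_prov(df, path, seed, sprintf("fs_hz: %g", fs))
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- read_csv_prov(path, required = "time")
  stop_if(ncol(df) < 2, sprintf("%s: no cell columns", basename(path)))
  time <- df$time
  stop_if(any(!is.finite(time)) || is.unsorted(time),
          sprintf("%s: malformed `time` column", basename(path)))
  fs <- 1 / stats::median(diff(time))
  list(traces = as.matrix(df[, -1, drop = FALSE]), time = time, fs = fs)
}

#' Write / read keypoint tables
#'
#' CSV layout: `time, centroid_x, centroid_y, nose_x, nose_y, tail_x,
#' tail_y` (seconds and cm).
#'
#' @param track a [behavior_track()].
#' @param path file path.
#' @param seed seed recorded in the provenance header.
#' @param arena fallback arena size when reading a file without one.
#' @return `read_keypoints_csv` returns a [behavior_track()].
#' @export
write_keypoints_csv <- function(track, path, seed = NA) {
  df <- data.frame(time = (seq_len(nrow(track$centroid)) - 1) / track$fs,
                   centroid_x = track$centroid[, 1],
                   centroid_y = track$centroid[, 2],
                   nose_x = track$nose[, 1], nose_y = track$nose[, 2],
                   tail_x = track$tailbase[, 1], tail_y = track$tailbase[, 2])
  write_csv_prov(df, path, seed,
                 c(sprintf("fs_hz: %g", track$fs),
                   sprintf("arena_cm: %g %g", track$arena[1], track$arena[2])))
}

#' @rdname write_keypoints_csv
#' @export
read_keypoints_csv <- function(path, arena = c(40, 40)) {
  need <- c("time", "centroid_x", "centroid_y", "nose_x", "nose_y",
            "tail_x", "tail_y")
  df <- read_csv_prov(path, required = need)
  fs <- 1 / stats::median(diff(df$time))
  hdr <- grep("^# arena_cm:", readLines(path, n = 10), value = TRUE)
  if (length(hdr) == 1)
    arena <- as.numeric(strsplit(sub("^# arena_cm: *", "", hdr[1]), " ")[[1]])
  behavior_track(fs = fs,
                 centroid = cbind(df$centroid_x, df$centroid_y),
                 nose = cbind(df$nose_x, df$nose_y),
                 tailbase = cbind(df$tail_x, df$tail_y),
                 arena = arena)
}

#' Write / read event tables (calcium or behavioral)
#'
#' @param events a data.frame (calcium events: `cell_id, onset, peak_time,
#'   amplitude, fwhm, zscore`; behavior events: `label, onset, offset,
#'   dh, target_id`).
#' @param path file path.
#' @param seed seed recorded in the provenance header.
#' @param required columns that must be present on read.
#' @return `read_events_csv` the data.frame.
#' @export
write_events_csv <- function(events, path, seed = NA) {
  write_csv_prov(events, path, seed)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path, required = c("onset")) {
  read_csv_prov(path, required = required)
}

#' Write / read a pipeline configuration as JSON
#'
#' Serialization round-trips losslessly; unknown keys are rejected on
#' read so typos fail loudly.
#'
#' @param config a [sim_config()] or plain named list of parameters.
#' @param path file path.
#' @return `read_config_json` returns a [sim_config()].
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  stop_if(length(unknown) > 0,
          sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  if (!is.null(raw$cluster_spec))
    raw$cluster_spec <- as.data.frame(raw$cluster_spec)
  do.call(sim_config, raw)
}
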
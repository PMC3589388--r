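#' Write a session recording to disk
#'
#' Three plain-text files in `out_dir`: `spikes.tsv` (unit_id, time_s),
#' `events.tsv` (time_s, event_type, payload) and `meta.json` (seed, phase
#' boundaries, unit positions and labels, content hashes of the two data
#' files).  Output is byte-stable for identical input.
#'
#' @param recording a `session_recording`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of file paths.
#' @export
write_session <- function(recording, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spikes_path <- file.path(out_dir, "spikes.tsv")
  events_path <- file.path(out_dir, "events.tsv")
  meta_path <- file.path(out_dir, "meta.json")

  sp <- recording$spikes
  sp$time_s <- sprintf("%.6f", sp$time_s)
  write.table(sp, spikes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- recording$events
  ev$time_s <- sprintf("%.6f", ev$time_s)
  write.table(ev, events_path, sep = "\t", quote = FALSE, row.names = FALSE)

  meta <- recording$meta
  meta$final_weights <- NULL            # provenance lives in the network file
  meta$spikes_md5 <- unname(tools::md5sum(spikes_path))
  meta$events_md5 <- unname(tools::md5sum(events_path))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, force = TRUE)
  invisible(list(spikes = spikes_path, events = events_path,
                 meta = meta_path))
}

#' Read a session recording from disk
#'
#' Validates the schema (column names, non-negative sorted times, phase
#' coverage) and reconstructs the `session_recording`.
#'
#' @param dir directory holding `spikes.tsv`, `events.tsv`, `meta.json`.
#' @return a `session_recording`.
#' @export
read_session <- function(dir) {
  paths <- file.path(dir, c("spikes.tsv", "events.tsv", "meta.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    sp_stop(paste("missing session component(s):",
                  paste(basename(missing), collapse = ", ")),
            "stimplast_io_error")
  spikes <- read.table(paths[1], header = TRUE, sep = "\t",
                       colClasses = c("integer", "numeric"))
  if (!identical(names(spikes), c("unit_id", "time_s")))
    sp_stop("spikes.tsv: expected columns unit_id, time_s",
            "stimplast_parse_error")
  events <- read.table(paths[2], header = TRUE, sep = "\t",
                       colClasses = c("numeric", "character", "character"),
                       na.strings = NULL)
  events$payload[is.na(events$payload)] <- ""
  if (!identical(names(events), c("time_s", "event_type", "payload")))
    sp_stop("events.tsv: expected columns time_s, event_type, payload",
            "stimplast_parse_error")
  if (nrow(spikes) && any(spikes$time_s < 0))
    sp_stop("spikes.tsv: negative spike time", "stimplast_validation_error")
  by_unit <- split(spikes$time_s, spikes$unit_id)
  if (any(vapply(by_unit, is.unsorted, logical(1))))
    sp_stop("spikes.tsv: spike times must be sorted within unit",
            "stimplast_validation_error")
  meta <- jsonlite::fromJSON(paths[3], simplifyDataFrame = TRUE)
  meta$phases <- as.data.frame(meta$phases, stringsAsFactors = FALSE)
  if (nrow(events) &&
      any(events$time_s > max(meta$phases$end_s) + 1e-9))
    sp_stop("events.tsv: event beyond the last phase boundary",
            "stimplast_validation_error")
  if (!is.null(meta$positions))
    meta$positions <- as.data.frame(meta$positions, stringsAsFactors = FALSE)
  session_recording(spikes, events, meta)
}
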
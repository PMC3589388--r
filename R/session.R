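#' Construct a session recording
#'
#' The common currency between the simulator, the synthetic-session
#' generator and the analysis pipeline: spike table, stimulus-event table
#' and metadata, segmented into the session's phases.
#'
#' @param spikes data.frame with columns `unit_id` (integer) and `time_s`
#'   (seconds from session start).
#' @param events data.frame with columns `time_s`, `event_type`
#'   (`touch` | `microstim_pulse` | `phase_boundary`) and `payload`.
#' @param meta list: `seed`, `phases` (data.frame `label`, `start_s`,
#'   `end_s`), optionally `positions`, `populations`, `reference_unit`,
#'   `units`, `config_hash`.
#' @return object of class `session_recording`.
#' @export
session_recording <- function(spikes, events, meta) {
  stopifnot(all(c("unit_id", "time_s") %in% names(spikes)),
            all(c("time_s", "event_type") %in% names(events)))
  if (nrow(spikes) && any(spikes$time_s < 0))
    sp_stop("spike times must be non-negative", "stimplast_validation_error")
  if (is.null(meta$phases))
    sp_stop("meta$phases is required", "stimplast_validation_error")
  if (is.null(meta$units))
    meta$units <- sort(unique(spikes$unit_id))
  spikes <- spikes[order(spikes$unit_id, spikes$time_s), , drop = FALSE]
  rownames(spikes) <- NULL
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(spikes = spikes, events = events, meta = meta),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  ph <- x$meta$phases
  cat(sprintf("<session_recording> %d units, %d spikes, %d events\n",
              length(x$meta$units), nrow(x$spikes), nrow(x$events)))
  for (i in seq_len(nrow(ph)))
    cat(sprintf("  %-12s %7.1f - %7.1f s\n", ph$label[i], ph$start_s[i],
                ph$end_s[i]))
  invisible(x)
}

event_df <- function(times, type, payload = "") {
  data.frame(time_s = as.numeric(times),
             event_type = rep_len(type, length(times)),
             payload = rep_len(payload, length(times)),
             stringsAsFactors = FALSE)
}

phase_window <- function(recording, phase) {
  ph <- recording$meta$phases
  i <- match(phase, ph$label)
  if (is.na(i))
    sp_stop(sprintf("unknown phase '%s' (have: %s)", phase,
                    paste(ph$label, collapse = ", ")),
            "stimplast_argument_error")
  c(ph$start_s[i], ph$end_s[i])
}

#' Extract per-unit spike trains for one phase
#'
#' @param recording a `session_recording`.
#' @param phase phase label.
#' @param units unit ids (default: all units in the recording).
#' @return named list of numeric vectors of spike times (s), one per unit.
#' @export
phase_spikes <- function(recording, phase, units = recording$meta$units) {
  win <- phase_window(recording, phase)
  sp <- recording$spikes
  sp <- sp[sp$time_s >= win[1] & sp$time_s < win[2] &
             sp$unit_id %in% units, , drop = FALSE]
  out <- split(sp$time_s, factor(sp$unit_id, levels = units))
  lapply(out, as.numeric)
}

#' Stimulus-event times of one type within a phase
#'
#' @inheritParams phase_spikes
#' @param type event type (`"touch"` or `"microstim_pulse"`).
#' @export
phase_events <- function(recording, phase, type = "touch") {
  win <- phase_window(recording, phase)
  ev <- recording$events
  ev$time_s[ev$event_type == type & ev$time_s >= win[1] & ev$time_s < win[2]]
}

#' Trial-align a spike train around stimulus events
#'
#' @param train spike times in seconds.
#' @param events stimulus times in seconds.
#' @param range_ms peristimulus window in ms.
#' @return list of numeric vectors (ms relative to each event).
#' @export
align_trials <- function(train, events, range_ms = c(-250, 300)) {
  lapply(events, function(e) {
    rel <- (train - e) * 1000
    rel[rel >= range_ms[1] & rel < range_ms[2]]
  })
}
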
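#' Gaussian-kernel peristimulus time histogram
#'
#' Aligns a spike train on stimulus events and smooths the trial-averaged
#' rate with a Gaussian density kernel (sigma = `kernel_sigma_ms`,
#' truncated at three sigma), evaluated on a 1 ms grid.  Baseline mean and
#' SD of the rate are computed over the pre-stimulus window
#' `[-250, 0)` ms.
#'
#' @param train spike times in seconds.
#' @param events stimulus times in seconds (at least one).
#' @param range_ms peristimulus window (ms).
#' @param kernel_sigma_ms Gaussian kernel sigma (ms).
#' @param baseline_ms baseline window (ms, within `range_ms`).
#' @return object of class `psth_result`: `bin_centers_ms`, `rate_hz`,
#'   `n_trials`, `baseline_mean_hz`, `baseline_sd_hz`.
#' @export
compute_psth <- function(train, events, range_ms = c(-250, 300),
                         kernel_sigma_ms = 20, baseline_ms = c(-250, 0)) {
  if (length(events) < 1)
    sp_stop("at least one stimulus event is required",
            "stimplast_argument_error")
  centers <- seq(range_ms[1] + 0.5, range_ms[2] - 0.5, by = 1)
  # 1 ms binning, padded by 3 sigma so the crop has no kernel edge bias
  pad <- ceiling(3 * kernel_sigma_ms)
  lo <- range_ms[1] - pad
  hi <- range_ms[2] + pad
  rel <- unlist(lapply(events, function(e) {
    r <- (train - e) * 1000
    r[r >= lo & r < hi]
  }), use.names = FALSE)
  n_bins <- hi - lo
  counts <- tabulate(findInterval(rel, seq(lo, hi, by = 1)), nbins = n_bins)
  kern <- dnorm(seq(-pad, pad), sd = kernel_sigma_ms)
  kern <- kern / sum(kern)
  sm <- stats::convolve(counts, rev(kern), type = "open")
  sm <- sm[(pad + 1):(pad + n_bins)]
  rate <- sm / length(events) * 1000                   # Hz
  keep <- (seq(lo, hi - 1) + 0.5) >= range_ms[1] &
          (seq(lo, hi - 1) + 0.5) < range_ms[2]
  rate <- pmax(rate[keep], 0)
  bl <- centers >= baseline_ms[1] & centers < baseline_ms[2]
  structure(list(bin_centers_ms = centers, rate_hz = rate,
                 n_trials = length(events),
                 baseline_mean_hz = mean(rate[bl]),
                 baseline_sd_hz = stats::sd(rate[bl])),
            class = "psth_result")
}

#' Touch-response metrics from a PSTH
#'
#' Peak rate and its latency within the response window, area under the
#' response curve above baseline, response sharpness (peak rate divided by
#' the temporal width of the response curve at three baseline SDs above
#' baseline), and the responsiveness flag: a unit is touch-responsive when
#' its peak rate exceeds `baseline + sd_criterion * baseline SD`.
#'
#' @param psth a `psth_result`.
#' @param response_window_ms post-stimulus analysis window (ms).
#' @param sd_criterion SD multiplier of the responsiveness threshold.
#' @return object of class `response_metrics`: `peak_rate_hz`,
#'   `latency_ms`, `auc`, `sharpness_hz_per_ms`, `responsive`,
#'   `baseline_mean_hz`, `baseline_sd_hz`.
#' @export
response_metrics <- function(psth, response_window_ms = c(0, 70),
                             sd_criterion = 3) {
  ct <- psth$bin_centers_ms
  win <- ct >= response_window_ms[1] & ct < response_window_ms[2]
  if (!any(win) || min(ct) > -1)
    sp_stop("PSTH must cover the baseline and response windows",
            "stimplast_argument_error")
  r <- psth$rate_hz[win]
  peak <- max(r)
  latency <- ct[win][which.max(r)]
  base <- psth$baseline_mean_hz
  bsd <- psth$baseline_sd_hz
  auc <- sum(pmax(r - base, 0)) / 1000       # spikes (Hz x s) above baseline
  degenerate <- (bsd == 0)
  responsive <- if (degenerate) peak > base else peak > base + sd_criterion * bsd

  sharp <- NA_real_
  if (responsive && !degenerate) {
    lev <- base + sd_criterion * bsd
    above <- psth$rate_hz >= lev
    ipk <- which(ct == latency)
    lo <- ipk
    while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- ipk
    while (hi < length(ct) && above[hi + 1]) hi <- hi + 1
    width <- ct[hi] - ct[lo] + 1             # ms at the criterion level
    sharp <- peak / width
  }
  structure(list(peak_rate_hz = peak, latency_ms = latency, auc = auc,
                 sharpness_hz_per_ms = sharp, responsive = responsive,
                 degenerate_baseline = degenerate,
                 baseline_mean_hz = base, baseline_sd_hz = bsd),
            class = "response_metrics")
}

#' Sliding-window Fano factor time course
#'
#' Across-trial variance-to-mean ratio of spike counts in 20 ms windows
#' shifted in 3 ms steps across the peristimulus range.  Windows with zero
#' mean count are reported as `NA` (0/0 undefined) and excluded from
#' ensemble averages.
#'
#' @param trials list of spike-time vectors (ms, peristimulus), one per
#'   trial; at least two trials.
#' @param window_ms window width.
#' @param step_ms window shift.
#' @param range_ms peristimulus range covered.
#' @return object of class `fano_timecourse`: `window_centers_ms`, `fano`.
#' @export
fano_timecourse <- function(trials, window_ms = 20, step_ms = 3,
                            range_ms = c(-250, 300)) {
  if (length(trials) < 2)
    sp_stop("at least two trials are required", "stimplast_argument_error")
  starts <- seq(range_ms[1], range_ms[2] - window_ms, by = step_ms)
  counts <- vapply(trials, function(tr) {
    vapply(starts, function(s) sum(tr >= s & tr < s + window_ms), numeric(1))
  }, numeric(length(starts)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(starts))
  mu <- rowMeans(counts)
  va <- apply(counts, 1, stats::var)
  fano <- ifelse(mu > 0, va / mu, NA_real_)
  structure(list(window_centers_ms = starts + window_ms / 2, fano = fano,
                 window_ms = window_ms, step_ms = step_ms,
                 mean_count = mu),
            class = "fano_timecourse")
}

#' Ensemble Fano factor and its stimulus-induced reduction
#'
#' Averages per-unit Fano time courses (NA windows excluded) and reports
#' the percentage decrease from the mean baseline (pre-stimulus) Fano
#' factor to the trough (minimum) of the ensemble-mean Fano curve within
#' the post-onset response window; the mean response-window value is also
#' reported.
#'
#' @param recording a `session_recording`.
#' @param phase phase label.
#' @param units unit ids (default: cortical/analyzed units).
#' @param range_ms,window_ms,step_ms see [fano_timecourse()].
#' @param baseline_ms,response_ms windows for the reduction summary.
#' @return list: `window_centers_ms`, `fano` (ensemble mean),
#'   `baseline_fano`, `response_fano`, `trough_fano`, `decrease_pc`.
#' @export
ensemble_fano <- function(recording, phase, units = analysis_units(recording),
                          range_ms = c(-250, 300), window_ms = 20, step_ms = 3,
                          baseline_ms = c(-250, 0), response_ms = c(0, 70)) {
  ev <- phase_events(recording, phase, "touch")
  if (length(ev) < 2)
    sp_stop("phase has fewer than two touch events", "stimplast_argument_error")
  trains <- phase_spikes(recording, phase, units)
  mats <- lapply(trains, function(tr) {
    fano_timecourse(align_trials(tr, ev, range_ms), window_ms, step_ms,
                    range_ms)$fano
  })
  fmat <- do.call(rbind, mats)
  fano <- colMeans(fmat, na.rm = TRUE)
  ctrs <- seq(range_ms[1], range_ms[2] - window_ms, by = step_ms) + window_ms / 2
  blw <- ctrs >= baseline_ms[1] & ctrs < baseline_ms[2]
  rsw <- ctrs >= response_ms[1] & ctrs < response_ms[2] + window_ms / 2
  baseline_fano <- mean(fano[blw], na.rm = TRUE)
  response_fano <- mean(fano[rsw], na.rm = TRUE)
  trough <- min(fano[rsw], na.rm = TRUE)
  list(window_centers_ms = ctrs, fano = fano,
       baseline_fano = baseline_fano, response_fano = response_fano,
       trough_fano = trough,
       decrease_pc = 100 * (baseline_fano - trough) / baseline_fano)
}

# units entering ensemble analyses: cortical units when the recording comes
# from the simulator, all units otherwise (synthetic sessions)
analysis_units <- function(recording) {
  recording$meta$cortical_units %||% recording$meta$units
}

#' Per-unit response metrics for a phase
#'
#' @param recording a `session_recording`.
#' @param phase phase label.
#' @param units unit ids.
#' @param ... passed to [compute_psth()] / [response_metrics()].
#' @return data.frame, one row per unit, with the response metrics.
#' @export
phase_response_metrics <- function(recording, phase,
                                   units = analysis_units(recording), ...) {
  ev <- phase_events(recording, phase, "touch")
  if (length(ev) < 1)
    sp_stop(sprintf("phase '%s' has no touch events", phase),
            "stimplast_argument_error")
  trains <- phase_spikes(recording, phase, units)
  rows <- lapply(seq_along(units), function(i) {
    m <- response_metrics(compute_psth(trains[[i]], ev), ...)
    data.frame(unit_id = units[i], peak_rate_hz = m$peak_rate_hz,
               latency_ms = m$latency_ms, auc = m$auc,
               sharpness_hz_per_ms = m$sharpness_hz_per_ms,
               responsive = m$responsive,
               baseline_mean_hz = m$baseline_mean_hz,
               baseline_sd_hz = m$baseline_sd_hz)
  })
  do.call(rbind, rows)
}

#' Touch-responsive units of a phase
#' @inheritParams phase_response_metrics
#' @return unit ids passing the 3 SD responsiveness criterion.
#' @export
responsive_units <- function(recording, phase,
                             units = analysis_units(recording)) {
  m <- phase_response_metrics(recording, phase, units)
  m$unit_id[m$responsive]
}

#' Classify units by before/after responsiveness
#'
#' Four categories: responsive in both tactile phases (`always`), only
#' before (`before_only`), only after (`after_only`), or in neither
#' (`never`).
#'
#' @param before,after data.frames from [phase_response_metrics()] over the
#'   same unit set.
#' @return list: `labels` (data.frame `unit_id`, `category`) and
#'   `proportions` (named numeric, sums to 1).
#' @export
classify_responsiveness <- function(before, after) {
  if (!identical(before$unit_id, after$unit_id))
    sp_stop("before/after unit sets differ", "stimplast_argument_error")
  cat <- ifelse(before$responsive & after$responsive, "always",
         ifelse(before$responsive & !after$responsive, "before_only",
         ifelse(!before$responsive & after$responsive, "after_only", "never")))
  lv <- c("always", "before_only", "after_only", "never")
  prop <- as.numeric(table(factor(cat, levels = lv))) / length(cat)
  list(labels = data.frame(unit_id = before$unit_id, category = cat,
                           stringsAsFactors = FALSE),
       proportions = stats::setNames(prop, lv))
}
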
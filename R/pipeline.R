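#' Analyze one tactile phase of a session
#'
#' Computes per-unit touch-response metrics, the ensemble Fano time course
#' and its stimulus-induced reduction, and the information measures
#' (shuffle-corrected pairwise MI and sub-ensemble multi-information) over
#' the phase.
#'
#' @param recording a `session_recording`.
#' @param phase phase label (`tactile_pre` or `tactile_post`).
#' @param units analyzed unit ids.
#' @param bin_ms MI bin width.
#' @param n_shuffles shuffle surrogates for bias correction.
#' @param mi_units optional cap on the number of units entering the MI /
#'   multi-information computation (first `mi_units` ids; NULL = all).
#' @param subensemble_size,n_subensembles multi-information settings.
#' @param seed RNG seed for shuffles and sub-ensembles.
#' @return list of class `phase_analysis`.
#' @export
analyze_phase <- function(recording, phase,
                          units = analysis_units(recording), bin_ms = 10,
                          n_shuffles = 20, mi_units = NULL,
                          subensemble_size = 5, n_subensembles = 50,
                          seed = 1) {
  metrics <- phase_response_metrics(recording, phase, units)
  fano <- ensemble_fano(recording, phase, units)
  mi_ids <- if (is.null(mi_units)) units else head(units, mi_units)
  ref <- recording$meta$reference_unit
  if (!is.null(mi_units) && !is.null(ref) && !is.na(ref) &&
      ref %in% units && !(ref %in% mi_ids))
    mi_ids[length(mi_ids)] <- ref
  counts <- bin_spike_counts(recording, phase, bin_ms, mi_ids)
  info <- mi_matrix(counts, n_shuffles, seed = seed)
  multi <- multi_information(counts, subensemble_size, n_subensembles,
                             n_shuffles, seed = seed)
  structure(list(phase = phase, units = units, metrics = metrics,
                 fano = fano, counts = counts, info = info, multi = multi),
            class = "phase_analysis")
}

#' Compare the pre- and post-conditioning tactile phases
#'
#' The session-level before/after summary: ensemble response metrics
#' (averaged over units responsive in both phases), baseline rate over all
#' units, baseline Fano factor and stimulus-induced Fano reduction, mean
#' pairwise MI and multi-information, the responsiveness classification,
#' and the trigger-pair contrast when a reference unit is known.
#'
#' @param recording a `session_recording`.
#' @param ... passed to [analyze_phase()].
#' @return list of class `session_comparison_full`: `pre`, `post`
#'   (phase analyses), `summary` (metric table with percentage changes),
#'   `classification`, `trigger_contrast`.
#' @export
compare_phases <- function(recording, ...) {
  pre <- analyze_phase(recording, "tactile_pre", ...)
  post <- analyze_phase(recording, "tactile_post", ...)

  both <- pre$metrics$responsive & post$metrics$responsive
  mean_of <- function(an, col, sel) {
    v <- an$metrics[[col]][sel]
    mean(v[is.finite(v)])
  }
  sharp_ok <- both & is.finite(pre$metrics$sharpness_hz_per_ms) &
    is.finite(post$metrics$sharpness_hz_per_ms)

  mi_pre <- mean(pre$info$mi_matrix[upper.tri(pre$info$mi_matrix)])
  mi_post <- mean(post$info$mi_matrix[upper.tri(post$info$mi_matrix)])
  mean_upper <- function(M) mean(M[upper.tri(M)], na.rm = TRUE)
  r_pre <- mean_upper(suppressWarnings(stats::cor(t(pre$counts$counts))))
  r_post <- mean_upper(suppressWarnings(stats::cor(t(post$counts$counts))))

  vals <- rbind(
    data.frame(metric = "peak_rate_hz",
               before = mean_of(pre, "peak_rate_hz", both),
               after = mean_of(post, "peak_rate_hz", both)),
    data.frame(metric = "auc",
               before = mean_of(pre, "auc", both),
               after = mean_of(post, "auc", both)),
    data.frame(metric = "sharpness_hz_per_ms",
               before = mean_of(pre, "sharpness_hz_per_ms", sharp_ok),
               after = mean_of(post, "sharpness_hz_per_ms", sharp_ok)),
    data.frame(metric = "baseline_rate_hz",
               before = mean(pre$metrics$baseline_mean_hz),
               after = mean(post$metrics$baseline_mean_hz)),
    data.frame(metric = "fano_baseline",
               before = pre$fano$baseline_fano,
               after = post$fano$baseline_fano),
    data.frame(metric = "fano_decrease_pc",
               before = pre$fano$decrease_pc,
               after = post$fano$decrease_pc),
    data.frame(metric = "mean_mi_bits", before = mi_pre, after = mi_post),
    data.frame(metric = "multi_info_bits",
               before = pre$multi$multi_info_bits,
               after = post$multi$multi_info_bits),
    data.frame(metric = "mean_correlation", before = r_pre, after = r_post))
  vals$pc <- ifelse(vals$before != 0,
                    100 * (vals$after - vals$before) / vals$before, NA_real_)

  cls <- classify_responsiveness(pre$metrics, post$metrics)
  ref <- recording$meta$reference_unit
  trig <- NULL
  if (!is.null(ref) && !is.na(ref) && ref %in% pre$info$units)
    trig <- trigger_pair_contrast(pre$info, post$info, ref)

  structure(list(pre = pre, post = post, summary = vals,
                 classification = cls, trigger_contrast = trig),
            class = "session_comparison_full")
}

#' @export
print.session_comparison_full <- function(x, ...) {
  cat("Before/after tactile-phase comparison\n")
  s <- x$summary
  s$before <- signif(s$before, 4); s$after <- signif(s$after, 4)
  s$pc <- signif(s$pc, 3)
  print(s, row.names = FALSE)
  cat("\nResponsiveness proportions:\n")
  print(round(x$classification$proportions, 3))
  if (!is.null(x$trigger_contrast))
    cat(sprintf("\nPairs with increased MI: trigger %.0f%%, non-trigger %.0f%%\n",
                100 * x$trigger_contrast$prop_increased_trigger,
                100 * x$trigger_contrast$prop_increased_nontrigger))
  invisible(x)
}

#' Run a full simulated experiment
#'
#' Builds the network, assembles the three-phase session for the requested
#' conditioning mode, runs the event-driven simulation and the before/after
#' analysis.
#'
#' @param config a `tc_config` (default 1980-neuron model).
#' @param mode conditioning mode (`spike_triggered`, `random`,
#'   `persistent_touch`, `none`).
#' @param durations_s length-3 phase durations (s).
#' @param seed integer seed driving network construction, schedules and
#'   background activity.
#' @param analyze run the analysis pipeline (set FALSE to return the raw
#'   recording only).
#' @param ... passed to [compare_phases()].
#' @return list: `network`, `schedule`, `recording`, and (when `analyze`)
#'   `comparison`.
#' @export
run_experiment <- function(config = default_model_config(),
                           mode = "spike_triggered",
                           durations_s = c(100, 100, 100), seed = 1,
                           analyze = TRUE, ...) {
  network <- build_network(config, seed = seed)
  schedule <- build_session(mode, durations_s, network, seed = seed)
  recording <- run_simulation(network, schedule, seed = seed)
  out <- list(network = network, schedule = schedule, recording = recording)
  if (analyze) out$comparison <- compare_phases(recording, ...)
  out
}

#' Run a batch of seeded conditioning experiments
#'
#' Repeats [run_experiment()] across seeds and collects the session-level
#' percentage changes and summary quantities used for the before/after
#' claims: PSTH peak, above-baseline area, sharpness, baseline rate,
#' stimulus-induced Fano reduction (per phase), mean pairwise MI,
#' multi-information, and the responsiveness partition.
#'
#' @param n_seeds number of independent seeded runs.
#' @param seed base seed; run `i` uses `seed * 100 + i`.
#' @param config a `tc_config`.
#' @param mode conditioning mode.
#' @param durations_s phase durations (s).
#' @param ... passed to [compare_phases()].
#' @return data.frame, one row per run, with columns `seed`, `peak_pc`,
#'   `auc_pc`, `sharpness_pc`, `baseline_pc`, `mi_pc`, `multi_pc`,
#'   `fano_decrease_pre`, `fano_decrease_post`, `baseline_hz`,
#'   `prop_always`, `prop_before_only`, `prop_after_only`, `prop_never`.
#' @export
run_conditioning_batch <- function(n_seeds = 10, seed = 1,
                                   config = default_model_config(scale = 1),
                                   mode = "spike_triggered",
                                   durations_s = c(100, 100, 100), ...) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    s <- seed * 100 + i
    res <- run_experiment(config, mode, durations_s, seed = s, ...)
    sm <- res$comparison$summary
    g <- function(m, col = "pc") sm[[col]][sm$metric == m]
    pr <- res$comparison$classification$proportions
    data.frame(seed = s,
               peak_pc = g("peak_rate_hz"),
               auc_pc = g("auc"),
               sharpness_pc = g("sharpness_hz_per_ms"),
               baseline_pc = g("baseline_rate_hz"),
               mi_pc = g("mean_mi_bits"),
               multi_pc = g("multi_info_bits"),
               fano_decrease_pre = g("fano_decrease_pc", "before"),
               fano_decrease_post = g("fano_decrease_pc", "after"),
               baseline_hz = g("baseline_rate_hz", "before"),
               prop_always = pr[["always"]],
               prop_before_only = pr[["before_only"]],
               prop_after_only = pr[["after_only"]],
               prop_never = pr[["never"]])
  })
  do.call(rbind, rows)
}
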
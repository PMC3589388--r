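#' Run an event-driven network simulation
#'
#' Processes the session's global event queue (stimulus events, per-neuron
#' Poisson background drive, synaptic deliveries with conduction delays) in
#' time order with deterministic tie-breaking, applying the
#' integrate-and-fire rules (threshold, depolarization blockade, absolute
#' and relative refractoriness) and additive STDP on plastic synapses.  In
#' `spike_triggered` mode microstimulation pulses are generated online,
#' `trigger_delay_ms` after each reference-unit spike within the
#' conditioning phase.  Identical `(network, schedule, seed)` give
#' bit-identical recordings.
#'
#' @param network a `tc_network`.
#' @param schedule a `stimulation_schedule` from [build_session()].
#' @param seed integer seed for the background-drive stream.
#' @param max_spikes abort threshold guarding against runaway activity.
#' @return a [session_recording()]; `meta$final_weights` holds the
#'   post-session synaptic weights.
#' @export
run_simulation <- function(network, schedule, seed = 1, max_spikes = 5e7) {
  stopifnot(inherits(network, "tc_network"),
            inherits(schedule, "stimulation_schedule"))
  cfg <- network$config
  pops <- network$populations
  classes <- pops$cell_class
  cp <- lapply(classes, function(cl) cfg$cell_params[[cl]])

  pop_tau <- t(vapply(cp, function(p) p$tau_receptor[CHANNELS], numeric(3)))
  pop_E <- t(vapply(cp, function(p) p$reversal[CHANNELS], numeric(3)))
  num <- function(f) vapply(cp, function(p) p[[f]], numeric(1))

  syn <- network$synapses
  duration_ms <- max(schedule$phases$end_s) * 1000
  cond <- schedule$phases[schedule$phases$label == "conditioning", ]
  ref <- schedule$reference_unit
  closed_loop <- schedule$mode == "spike_triggered" && !is.na(ref)

  res <- .run_engine_cpp(
    pop_idx = match(network$neurons$pop, pops$name) - 1L,
    pop_tau = pop_tau, pop_E = pop_E,
    pop_vth = num("v_threshold"), pop_vblock = num("v_block"),
    pop_refrac = num("refrac_abs"), pop_R = num("refrac_R"),
    pop_tauR = num("tau_R"), pop_H = num("refrac_H"), pop_tauH = num("tau_H"),
    syn_pre = syn$pre - 1L, syn_post = syn$post - 1L,
    syn_channel = match(syn$channel, CHANNELS) - 1L,
    syn_weight = syn$weight, syn_wbase = syn$weight_baseline,
    syn_delay = syn$delay, syn_plastic = syn$plastic,
    stdp_eps_frac = cfg$stdp$increment_frac,
    stdp_window = cfg$stdp$window_ms,
    wmax_factor = cfg$stdp$wmax_factor,
    bg_rate_hz = cfg$background$rate_hz, bg_weight = cfg$background$weight,
    bg_shared_rate_hz = cfg$background$shared_rate_hz %||% 0,
    bg_shared_weight = cfg$background$shared_weight %||% 0,
    touch_times = schedule$touch_events * 1000,
    touch_targets = schedule$touch_targets - 1L,
    touch_weight = cfg$stim$touch_weight,
    touch_spread_ms = cfg$stim$touch_spread_ms %||% 0,
    touch_jitter_ms = cfg$stim$touch_jitter_ms %||% 0,
    pulse_times = schedule$microstim_pulses * 1000,
    pulse_targets = schedule$microstim_targets - 1L,
    pulse_weight = cfg$stim$microstim_weight,
    ext_times = numeric(0), ext_targets = integer(0),
    ext_weights = numeric(0),
    pulse_doublet_ms = cfg$stim$doublet_interval_ms %||% 0,
    reference_id = if (closed_loop) ref - 1L else -1L,
    cond_start = cond$start_s * 1000, cond_end = cond$end_s * 1000,
    stdp_t0 = if (identical(cfg$stdp$active_phase %||% "conditioning",
                            "conditioning")) cond$start_s * 1000 else 0,
    stdp_t1 = if (identical(cfg$stdp$active_phase %||% "conditioning",
                            "conditioning")) cond$end_s * 1000 else duration_ms,
    trigger_delay = schedule$trigger_delay_ms,
    lockout = schedule$trigger_lockout_ms,
    duration = duration_ms, seed = seed, max_spikes = max_spikes)

  spikes <- data.frame(unit_id = res$spike_id + 1L,
                       time_s = res$spike_t_ms / 1000)
  ev <- rbind(
    event_df(schedule$touch_events, "touch"),
    event_df(res$pulse_t_ms / 1000, "microstim_pulse"),
    event_df(schedule$phases$start_s, "phase_boundary",
             schedule$phases$label))

  meta <- list(
    seed = seed, mode = schedule$mode,
    config_hash = config_hash(cfg),
    phases = schedule$phases,
    units = network$neurons$id,
    positions = network$neurons[, c("id", "x", "y")],
    populations = network$neurons$pop,
    cortical_units = cortical_ids(network),
    reference_unit = schedule$reference_unit,
    touch_targets = schedule$touch_targets,
    microstim_targets = schedule$microstim_targets,
    final_weights = res$final_weights)
  session_recording(spikes, ev, meta)
}

#' Low-level event-driven simulation of an ad-hoc circuit
#'
#' Direct access to the event-driven engine for small hand-built circuits:
#' arbitrary synapse tables and per-event external inputs, no stimulus
#' protocol machinery.  The natural counterpart of the fixed-step
#' reference integrator [simulate_fixed_step()].
#'
#' @inheritParams simulate_fixed_step
#' @param bg_rate_hz,bg_weight optional Poisson background drive.
#' @param stdp_active STDP enabled over the whole run (default TRUE).
#' @param seed engine RNG seed (background drive only).
#' @return list with `spikes` (data.frame `unit_id`, `t_ms`) and `weights`.
#' @export
simulate_circuit <- function(cell_params, n_neurons, synapses, inputs,
                             duration_ms,
                             stdp = list(increment_frac = 0, window_ms = 10,
                                         wmax_factor = 5),
                             bg_rate_hz = 0, bg_weight = 0,
                             stdp_active = TRUE, seed = 0) {
  if (!is.null(cell_params$tau_receptor))
    cell_params <- rep(list(cell_params), n_neurons)
  pop_tau <- t(vapply(cell_params, function(p) p$tau_receptor[CHANNELS],
                      numeric(3)))
  pop_E <- t(vapply(cell_params, function(p) p$reversal[CHANNELS], numeric(3)))
  num <- function(f) vapply(cell_params, `[[`, numeric(1), f)
  n_syn <- nrow(synapses)
  res <- .run_engine_cpp(
    pop_idx = seq_len(n_neurons) - 1L,
    pop_tau = pop_tau, pop_E = pop_E,
    pop_vth = num("v_threshold"), pop_vblock = num("v_block"),
    pop_refrac = num("refrac_abs"), pop_R = num("refrac_R"),
    pop_tauR = num("tau_R"), pop_H = num("refrac_H"), pop_tauH = num("tau_H"),
    syn_pre = synapses$pre - 1L, syn_post = synapses$post - 1L,
    syn_channel = match(synapses$channel, CHANNELS) - 1L,
    syn_weight = synapses$weight, syn_wbase = synapses$weight_baseline,
    syn_delay = synapses$delay,
    syn_plastic = if (n_syn) synapses$plastic else logical(0),
    stdp_eps_frac = stdp$increment_frac, stdp_window = stdp$window_ms,
    wmax_factor = stdp$wmax_factor,
    bg_rate_hz = bg_rate_hz, bg_weight = bg_weight,
    bg_shared_rate_hz = 0, bg_shared_weight = 0,
    touch_times = numeric(0), touch_targets = integer(0), touch_weight = 0,
    touch_spread_ms = 0, touch_jitter_ms = 0,
    pulse_times = numeric(0), pulse_targets = integer(0), pulse_weight = 0,
    ext_times = inputs$time_ms, ext_targets = inputs$neuron - 1L,
    ext_weights = inputs$weight,
    pulse_doublet_ms = 0,
    reference_id = -1L, cond_start = 0, cond_end = 0,
    stdp_t0 = if (stdp_active) 0 else duration_ms + 1,
    stdp_t1 = if (stdp_active) duration_ms + 1 else duration_ms + 2,
    trigger_delay = 0, lockout = 0,
    duration = duration_ms, seed = seed, max_spikes = 1e7)
  list(spikes = data.frame(unit_id = res$spike_id + 1L, t_ms = res$spike_t_ms),
       weights = res$final_weights)
}
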
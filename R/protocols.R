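#' Tactile stimulation schedule with jittered period (model protocol)
#'
#' Inter-touch intervals are drawn uniformly within `period_range_ms`
#' (mean 600 ms), the cadence used when driving the network model.
#'
#' @param duration_s schedule length in seconds.
#' @param mean_period_ms mean inter-touch interval (ms).
#' @param period_range_ms length-2 range bracketing the mean.
#' @param seed RNG seed.
#' @return touch times in seconds within `[0, duration_s)`.
#' @export
make_touch_schedule <- function(duration_s, mean_period_ms = 600,
                                period_range_ms = c(400, 800), seed = 1) {
  if (period_range_ms[1] > period_range_ms[2] ||
      mean_period_ms < period_range_ms[1] || mean_period_ms > period_range_ms[2])
    sp_stop("period range must be ordered and bracket the mean",
            "stimplast_argument_error")
  if (duration_s <= 0) return(numeric(0))
  old <- set.seed_scoped(seed)
  on.exit(restore_seed(old))
  # centre the uniform draw on the requested mean
  half <- min(mean_period_ms - period_range_ms[1],
              period_range_ms[2] - mean_period_ms)
  n_max <- ceiling(duration_s * 1000 / period_range_ms[1]) + 1
  gaps <- runif(n_max, mean_period_ms - half, mean_period_ms + half)
  times <- cumsum(gaps) / 1000
  times[times < duration_s]
}

#' Random tactile schedule at a mean rate (experimental protocol)
#'
#' Homogeneous Poisson touch train, emulating in vivo sessions where the
#' tactile stimulus was applied randomly at a mean frequency of 0.5 Hz.
#'
#' @param duration_s schedule length in seconds.
#' @param mean_rate_hz mean touch rate.
#' @param seed RNG seed.
#' @return touch times in seconds.
#' @export
make_experimental_touch_schedule <- function(duration_s, mean_rate_hz = 0.5,
                                             seed = 1) {
  if (duration_s <= 0 || mean_rate_hz <= 0) return(numeric(0))
  old <- set.seed_scoped(seed)
  on.exit(restore_seed(old))
  n <- rpois(1, duration_s * mean_rate_hz)
  sort(runif(n, 0, duration_s))
}

#' Touch target set: relay cells closest to the sheet centre
#'
#' Natural touch is modelled as suprathreshold input to the fraction of
#' thalamocortical relay cells nearest the centre of the sheet,
#' representing a spatially contiguous receptive field.
#'
#' @param network a `tc_network`.
#' @param fraction fraction of relay cells targeted.
#' @return neuron ids, deterministic for a given network.
#' @export
touch_target_set <- function(network, fraction = 0.25) {
  relay <- network$neurons[network$neurons$pop == "relay", , drop = FALSE]
  if (!nrow(relay))
    sp_stop("network has no thalamic relay population",
            "stimplast_config_error")
  ctr <- network$config$sheet_extent_um / 2
  d <- euclidean_distance(cbind(relay$x, relay$y), c(ctr, ctr))
  k <- round(fraction * nrow(relay))
  relay$id[order(d)][seq_len(k)]
}

#' Microstimulation target set: random layer-5 pyramidal cells
#'
#' Microstimulation activates a random (non-contiguous) subset of layer-5
#' pyramidal neurons, reflecting activation of axons rather than somata
#' near the electrode.
#'
#' @param network a `tc_network`.
#' @param fraction fraction of L5 pyramidal cells targeted.
#' @param seed RNG seed.
#' @return neuron ids.
#' @export
microstim_target_set <- function(network, fraction = 0.10, seed = 1) {
  l5 <- pop_ids(network, "L5_pyr")
  if (!length(l5))
    sp_stop("network has no L5 pyramidal population",
            "stimplast_config_error")
  k <- round(fraction * length(l5))
  if (k == 0) return(integer(0))
  old <- set.seed_scoped(seed)
  on.exit(restore_seed(old))
  sort(sample(l5, k))
}

#' Spike-triggered microstimulation pulse times
#'
#' One pulse a fixed delay after each reference spike, with an optional
#' minimum inter-pulse lockout.
#'
#' @param reference_spikes_s sorted reference-unit spike times (s).
#' @param delay_ms trigger delay (default 5 ms).
#' @param lockout_ms minimum interval between pulses (default 0: none).
#' @return pulse times in seconds.
#' @export
spike_triggered_pulses <- function(reference_spikes_s, delay_ms = 5,
                                   lockout_ms = 0) {
  if (is.unsorted(reference_spikes_s))
    sp_stop("reference spike times must be sorted", "stimplast_argument_error")
  pulses <- reference_spikes_s + delay_ms / 1000
  if (lockout_ms > 0 && length(pulses) > 1) {
    keep <- rep(TRUE, length(pulses))
    last <- pulses[1]
    for (i in seq_along(pulses)[-1]) {
      if (pulses[i] - last < lockout_ms / 1000) keep[i] <- FALSE
      else last <- pulses[i]
    }
    pulses <- pulses[keep]
  }
  pulses
}

#' Random pulse train matched to reference statistics
#'
#' Generates inter-pulse intervals from a gamma distribution whose mean and
#' variance are moment-matched to the reference train's intervals, covering
#' the same time span.
#'
#' @param reference_pulses_s reference pulse times (s), at least two.
#' @param seed RNG seed.
#' @return pulse times in seconds within the reference span.
#' @export
random_pulses_matched <- function(reference_pulses_s, seed = 1) {
  if (length(reference_pulses_s) < 2)
    sp_stop("need at least two reference pulses", "stimplast_argument_error")
  ipi <- diff(sort(reference_pulses_s))
  m <- mean(ipi); v <- var(ipi)
  t0 <- min(reference_pulses_s); t1 <- max(reference_pulses_s)
  old <- set.seed_scoped(seed)
  on.exit(restore_seed(old))
  n_max <- ceiling(1.5 * length(ipi)) + 20
  gaps <- if (v <= .Machine$double.eps * m^2) {
    rep(m, n_max)                      # degenerate: regular train
  } else {
    rgamma(n_max, shape = m^2 / v, rate = m / v)
  }
  times <- t0 + cumsum(gaps)
  while (times[length(times)] < t1) {  # extend if undershooting the span
    extra <- if (v <= .Machine$double.eps * m^2) rep(m, n_max)
             else rgamma(n_max, shape = m^2 / v, rate = m / v)
    times <- c(times, times[length(times)] + cumsum(extra))
  }
  c(t0, times[times <= t1])
}

#' Assemble a three-phase stimulation session
#'
#' Phases `tactile_pre`, `conditioning`, `tactile_post`.  Touch events are
#' generated for the tactile phases (and for the conditioning phase in
#' `persistent_touch` mode); microstimulation is confined to the
#' conditioning phase.  In `spike_triggered` mode a reference unit is
#' designated (chosen from touch-responsive cortical cells outside the
#' stimulation target set, via a short pilot simulation, unless supplied)
#' and pulses are generated online during simulation, 5 ms after each
#' reference spike.  In `random` mode pulse times are pre-generated with
#' gamma inter-pulse intervals moment-matched to the reference statistics
#' (`random_reference` pulse train, or an expectation from `random_rate_hz`).
#'
#' @param mode `spike_triggered`, `random`, `persistent_touch` or `none`.
#' @param durations_s length-3 phase durations in seconds.
#' @param network a `tc_network`.
#' @param seed RNG seed.
#' @param reference_unit reference neuron id for `spike_triggered` mode
#'   (default: chosen by pilot simulation).
#' @param random_reference for `random` mode, a reference pulse train (s)
#'   whose statistics are matched; default: a previously recorded
#'   spike-triggered train simulated with the same seed.
#' @param touch_period use the model cadence (`"model"`: uniform 400-800 ms
#'   intervals) or the experimental Poisson 0.5 Hz cadence
#'   (`"experimental"`).
#' @return object of class `stimulation_schedule`.
#' @export
build_session <- function(mode = c("spike_triggered", "random",
                                   "persistent_touch", "none"),
                          durations_s = c(100, 100, 100),
                          network, seed = 1, reference_unit = NULL,
                          random_reference = NULL,
                          touch_period = c("model", "experimental")) {
  mode <- match.arg(mode)
  touch_period <- match.arg(touch_period)
  stopifnot(length(durations_s) == 3, all(durations_s >= 0))
  bounds <- cumsum(c(0, durations_s))
  phases <- data.frame(label = c("tactile_pre", "conditioning", "tactile_post"),
                       start_s = bounds[1:3], end_s = bounds[2:4],
                       stringsAsFactors = FALSE)

  touch_fun <- function(dur, s) {
    if (touch_period == "model") make_touch_schedule(dur, seed = s)
    else make_experimental_touch_schedule(dur, seed = s)
  }
  touch <- c(touch_fun(durations_s[1], seed) + bounds[1],
             touch_fun(durations_s[3], seed + 1000L) + bounds[3])
  if (mode == "persistent_touch")
    touch <- sort(c(touch, touch_fun(durations_s[2], seed + 2000L) + bounds[2]))

  cfg <- network$config$stim
  touch_targets <- touch_target_set(network, cfg$touch_fraction)
  microstim_targets <- integer(0)
  pulses <- numeric(0)
  ref <- NA_integer_

  if (mode %in% c("spike_triggered", "random")) {
    microstim_targets <- microstim_target_set(network, cfg$microstim_fraction,
                                              seed = seed + 3000L)
    if (mode == "spike_triggered") {
      ref <- if (!is.null(reference_unit)) as.integer(reference_unit)
             else choose_reference_unit(network, seed = seed + 4000L,
                                        exclude = microstim_targets)
    } else {
      if (is.null(random_reference)) {
        st <- build_session("spike_triggered", durations_s, network,
                            seed = seed, touch_period = touch_period)
        rec <- run_simulation(network, st, seed = seed)
        random_reference <- phase_events(rec, "conditioning", "microstim_pulse")
      }
      pulses <- if (length(random_reference) >= 2)
        random_pulses_matched(random_reference, seed = seed + 5000L)
      else numeric(0)
      pulses <- pulses[pulses >= bounds[2] & pulses < bounds[3]]
    }
  }

  structure(list(mode = mode, phases = phases, touch_events = touch,
                 touch_targets = touch_targets,
                 microstim_pulses = pulses,
                 microstim_targets = microstim_targets,
                 reference_unit = ref,
                 trigger_delay_ms = cfg$trigger_delay_ms,
                 trigger_lockout_ms = cfg$trigger_lockout_ms),
            class = "stimulation_schedule")
}

#' Choose a reference unit for spike-triggered stimulation
#'
#' Runs a short tactile-only pilot simulation and picks the most active
#' touch-responsive cortical unit outside `exclude`, mirroring the
#' experimental choice of a well-isolated, high-rate (~10 Hz) reference
#' channel.  Falls back to the cortical pyramidal cell closest to the
#' sheet centre when no unit passes the responsiveness criterion in the
#' pilot.
#'
#' @param network a `tc_network`.
#' @param seed RNG seed.
#' @param exclude neuron ids not eligible (e.g. microstimulation targets).
#' @param pilot_duration_s pilot length in seconds.
#' @return a neuron id.
#' @export
choose_reference_unit <- function(network, seed = 1, exclude = integer(0),
                                  pilot_duration_s = 15) {
  sched <- structure(list(
    mode = "none",
    phases = data.frame(label = c("tactile_pre", "conditioning", "tactile_post"),
                        start_s = c(0, pilot_duration_s, pilot_duration_s),
                        end_s = c(pilot_duration_s, pilot_duration_s,
                                  pilot_duration_s),
                        stringsAsFactors = FALSE),
    touch_events = make_touch_schedule(pilot_duration_s, seed = seed),
    touch_targets = touch_target_set(network,
                                     network$config$stim$touch_fraction),
    microstim_pulses = numeric(0), microstim_targets = integer(0),
    reference_unit = NA_integer_, trigger_delay_ms = 5,
    trigger_lockout_ms = 0), class = "stimulation_schedule")
  rec <- run_simulation(network, sched, seed = seed)
  units <- setdiff(cortical_ids(network), exclude)
  resp <- responsive_units(rec, "tactile_pre", units = units)
  if (length(resp)) {
    n_spk <- table(factor(rec$spikes$unit_id, levels = resp))
    return(as.integer(names(which.max(n_spk))))
  }
  ctr <- network$config$sheet_extent_um / 2
  pyr <- network$neurons[network$neurons$pop %in%
                           c("L2/3_pyr", "L4_pyr", "L5_pyr", "L6_pyr") &
                           !(network$neurons$id %in% exclude), , drop = FALSE]
  d <- euclidean_distance(cbind(pyr$x, pyr$y), c(ctr, ctr))
  pyr$id[which.min(d)]
}
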
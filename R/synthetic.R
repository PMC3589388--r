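#' Before/after effect specification (ground truth)
#'
#' Effect sizes injected between the pre- and post-conditioning tactile
#' phases of a synthetic session, all expressed as percentage changes
#' relative to the "before" phase.  Used by recovery tests: the analysis
#' pipeline must read back what was injected.
#'
#' @param peak_gain_pc percentage change of the (smoothed) PSTH peak rate
#'   of responsive units.
#' @param baseline_gain_pc percentage change of baseline firing rates.
#' @param fano_change_pc percentage change of the baseline Fano factor
#'   (20 ms windows).
#' @param correlation_change_pc percentage change of pairwise binned-count
#'   correlation.
#' @param trigger_correlation_change_pc extra correlation change applied
#'   only to pairs containing the reference unit.
#' @param transitions optional length-4 proportions
#'   `(always, before_only, after_only, never)` of responsiveness
#'   categories; overrides `responsive_fraction`.
#' @return list of class `before_after_effect`.
#' @export
before_after_effect <- function(peak_gain_pc = 0, baseline_gain_pc = 0,
                                fano_change_pc = 0,
                                correlation_change_pc = 0,
                                trigger_correlation_change_pc = 0,
                                transitions = NULL) {
  if (!is.null(transitions)) {
    stopifnot(length(transitions) == 4, abs(sum(transitions) - 1) < 1e-9)
  }
  structure(list(peak_gain_pc = peak_gain_pc,
                 baseline_gain_pc = baseline_gain_pc,
                 fano_change_pc = fano_change_pc,
                 correlation_change_pc = correlation_change_pc,
                 trigger_correlation_change_pc = trigger_correlation_change_pc,
                 transitions = transitions),
            class = "before_after_effect")
}

#' Synthetic ensemble specification
#'
#' Describes an experiment-like recorded ensemble: unit count (drawn as
#' 42 +/- 8 unless fixed), lognormal baseline rates around ~10 Hz (the in
#' vivo regime; use ~3 Hz for the model regime), touch-locked Gaussian
#' response bumps (sigma 10 ms) at per-unit latencies within 0-70 ms,
#' across-trial rate modulation setting the baseline Fano factor, and
#' pairwise count correlation induced by thinning from a shared mother
#' process.
#'
#' @param n_units number of units (default: drawn as `round(rnorm(42, 8))`
#'   at generation time).
#' @param baseline_rate_hz median baseline rate.
#' @param rate_sdlog lognormal spread of per-unit rates.
#' @param responsive_fraction fraction of touch-responsive units (used
#'   when `effect$transitions` is NULL; responsiveness then persists
#'   across phases).
#' @param latency_range_ms range of per-unit response latencies.
#' @param response_gain peak-to-baseline ratio of the (unsmoothed)
#'   response bump of responsive units.
#' @param bump_sigma_ms response bump width.
#' @param pairwise_correlation target binned-count correlation (10 ms
#'   bins) between unit pairs.
#' @param fano_baseline target baseline Fano factor (20 ms windows).
#' @param touch_rate_hz mean touch rate of the tactile phases.
#' @param effect a [before_after_effect()].
#' @return list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_units = NULL, baseline_rate_hz = 10,
                          rate_sdlog = 0.4, responsive_fraction = 0.56,
                          latency_range_ms = c(10, 50), response_gain = 3,
                          bump_sigma_ms = 10, pairwise_correlation = 0.05,
                          fano_baseline = 1.2, touch_rate_hz = 0.5,
                          effect = before_after_effect()) {
  stopifnot(baseline_rate_hz >= 0, responsive_fraction >= 0,
            responsive_fraction <= 1, pairwise_correlation >= 0,
            fano_baseline >= 1)
  if (latency_range_ms[1] < 0 || latency_range_ms[2] > 70)
    sp_stop("latencies must lie within the 0-70 ms response window",
            "stimplast_argument_error")
  structure(as.list(environment()), class = "ensemble_spec")
}

# homogeneous Poisson train on [0, duration_s)
rpois_train <- function(rate_hz, duration_s) {
  if (rate_hz <= 0 || duration_s <= 0) return(numeric(0))
  sort(runif(rpois(1, rate_hz * duration_s), 0, duration_s))
}

#' Homogeneous Poisson spike trains
#'
#' @param rate_hz firing rate.
#' @param n_trials number of independent trials.
#' @param duration_s trial length.
#' @param seed RNG seed.
#' @return list of spike-time vectors (s).
#' @export
generate_poisson_trains <- function(rate_hz, n_trials, duration_s, seed = 1) {
  stopifnot(rate_hz >= 0)
  old <- set.seed_scoped(seed)
  on.exit(restore_seed(old))
  lapply(seq_len(n_trials), function(k) rpois_train(rate_hz, duration_s))
}

#' Correlated spike-train pair by thinning from a shared mother process
#'
#' Both trains share thinned copies of a common Poisson mother train
#' (retention probability `sqrt(correlation)`) plus independent spikes,
#' giving binned-count correlation equal to the target.
#'
#' @param rate_hz per-train firing rate.
#' @param correlation target count correlation in `[0, 1]`.
#' @param duration_s train length.
#' @param seed RNG seed.
#' @return list of two spike-time vectors (s).
#' @export
generate_correlated_pair <- function(rate_hz, correlation, duration_s,
                                     seed = 1) {
  if (correlation < 0 || correlation > 1)
    sp_stop("correlation must lie in [0, 1]", "stimplast_argument_error")
  old <- set.seed_scoped(seed)
  on.exit(restore_seed(old))
  q <- sqrt(correlation)
  mother <- rpois_train(rate_hz, duration_s)
  take <- function() {
    shared <- mother[runif(length(mother)) < q]
    sort(c(shared, rpois_train(rate_hz * (1 - q), duration_s)))
  }
  list(take(), take())
}

# merge overlapping peristimulus windows; returns matrix [start, end]
merge_windows <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) me <- max(me, ends[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- starts[i]; me <- ends[i] }
  }
  cbind(c(out_s, ms), c(out_e, me))
}

# one tactile phase for all units; returns data.frame(unit_id, time_s)
# relative to phase start
synth_phase <- function(spec, unit_tbl, duration_s, touches, q_vec,
                        v_vec, amp_vec, mother_rate_hz) {
  n <- nrow(unit_tbl)
  win <- c(-0.25, 0.30)                     # peristimulus span carrying the
  mother <- rpois_train(mother_rate_hz, duration_s)  # trial-gain modulation
  keep_mother <- length(mother) > 0
  wins <- if (length(touches))
    merge_windows(pmax(touches + win[1], 0),
                  pmin(touches + win[2], duration_s)) else NULL
  spk <- vector("list", n)
  for (i in seq_len(n)) {
    lam_ind <- unit_tbl$rate_hz[i] - q_vec[i] * mother_rate_hz
    if (lam_ind < 0) lam_ind <- 0
    # independent component, trial windows modulated by a gamma gain
    base <- rpois_train(lam_ind, duration_s)
    if (!is.null(wins)) {
      inwin <- rep(FALSE, length(base))
      for (k in seq_len(nrow(wins)))
        inwin <- inwin | (base >= wins[k, 1] & base < wins[k, 2])
      base <- base[!inwin]
      extra <- lapply(seq_len(nrow(wins)), function(k) {
        span <- wins[k, 2] - wins[k, 1]
        g <- if (v_vec[i] > 0)
          rgamma(1, shape = 1 / v_vec[i], rate = 1 / v_vec[i]) else 1
        runif(rpois(1, lam_ind * span * g), wins[k, 1], wins[k, 2])
      })
      base <- c(base, unlist(extra, use.names = FALSE))
    }
    # shared component inducing pairwise correlation
    shared <- if (keep_mother && q_vec[i] > 0)
      mother[runif(length(mother)) < q_vec[i]] else numeric(0)
    # touch-locked Gaussian response bump
    bump <- numeric(0)
    if (amp_vec[i] > 0 && length(touches)) {
      mass <- amp_vec[i] * sqrt(2 * pi) * spec$bump_sigma_ms / 1000
      bump <- unlist(lapply(touches, function(tt) {
        nb <- rpois(1, mass)
        tt + rnorm(nb, unit_tbl$latency_ms[i], spec$bump_sigma_ms) / 1000
      }), use.names = FALSE)
      bump <- bump[bump >= 0 & bump < duration_s]
    }
    tr <- sort(c(base, shared, bump))
    spk[[i]] <- data.frame(unit_id = unit_tbl$unit_id[i], time_s = tr)
  }
  do.call(rbind, spk)
}

#' Generate a synthetic experiment-like session
#'
#' Three phases (tactile / conditioning / tactile) with Poisson touch
#' events, inhomogeneous-Poisson units carrying touch-locked response
#' bumps, a shared mother process inducing pairwise correlation,
#' across-trial gain modulation setting the baseline Fano factor, and the
#' `effect` fields applied exactly (in expectation, as measured by the
#' analysis pipeline) in the post phase.  Unit 1 acts as the reference
#' unit unless overridden.
#'
#' @param spec an [ensemble_spec()].
#' @param durations_s length-3 phase durations (s).
#' @param seed RNG seed.
#' @param conditioning_spikes generate baseline spiking during the
#'   conditioning phase (default TRUE).
#' @return a [session_recording()]; `meta$ground_truth` carries the
#'   per-unit parameters and injected effect.
#' @export
generate_session <- function(spec = ensemble_spec(),
                             durations_s = c(180, 1800, 180), seed = 1,
                             conditioning_spikes = TRUE) {
  stopifnot(inherits(spec, "ensemble_spec"), length(durations_s) == 3)
  old <- set.seed_scoped(seed)
  on.exit(restore_seed(old))
  eff <- spec$effect

  n <- spec$n_units %||% max(5L, round(rnorm(1, 42, 8)))
  rates <- spec$baseline_rate_hz * exp(rnorm(n, 0, spec$rate_sdlog) -
                                         spec$rate_sdlog^2 / 2)
  lat <- runif(n, spec$latency_range_ms[1], spec$latency_range_ms[2])

  # responsiveness categories
  if (!is.null(eff$transitions)) {
    cat_lv <- c("always", "before_only", "after_only", "never")
    ncat <- floor(eff$transitions * n)
    rem <- n - sum(ncat)
    if (rem > 0) {
      add <- order(eff$transitions * n - ncat, decreasing = TRUE)[seq_len(rem)]
      ncat[add] <- ncat[add] + 1
    }
    categories <- sample(rep(cat_lv, ncat))
  } else {
    categories <- ifelse(runif(n) < spec$responsive_fraction, "always", "never")
  }
  resp_pre <- categories %in% c("always", "before_only")
  resp_post <- categories %in% c("always", "after_only")

  # correlation plumbing: q_i = sqrt(rho * f10 * rate_i / mother_rate),
  # where f10 inflates count variance at the 10 ms analysis bin
  b10 <- 0.010; w20 <- 0.020
  f10 <- 1 + (spec$fano_baseline - 1) * b10 / w20
  # mother rate chosen at the geometric middle of its feasibility range
  # [rho*f10*max(rate), min(rate)/(rho*f10)]
  rho_eff <- max(spec$pairwise_correlation * f10, 1e-12)
  if (rho_eff > sqrt(min(rates) / max(rates)) && spec$pairwise_correlation > 0)
    sp_stop("correlation target unachievable for the given rates",
            "stimplast_argument_error")
  mother_rate <- sqrt(min(rates) * max(rates))
  q_pre <- sqrt(spec$pairwise_correlation * f10 * rates / mother_rate)
  if (any(q_pre > 1) || any(q_pre * mother_rate > rates))
    sp_stop("correlation target unachievable for the given rates",
            "stimplast_argument_error")
  q_post <- q_pre * sqrt(1 + eff$correlation_change_pc / 100)
  ref_unit <- 1L
  q_post[ref_unit] <- q_post[ref_unit] *
    sqrt(1 + eff$trigger_correlation_change_pc / 100)

  # Fano plumbing: FF(20 ms) = 1 + v * lam_ind^2 * w / lam  (independent
  # component modulated by a gamma trial gain of variance v)
  lam_ind_pre <- pmax(rates - q_pre * mother_rate, 0)
  v_from_ff <- function(ff, lam, lam_ind)
    ifelse(lam_ind > 0, (ff - 1) * lam / (lam_ind^2 * w20), 0)
  v_pre <- v_from_ff(spec$fano_baseline, rates, lam_ind_pre)
  ff_post <- spec$fano_baseline * (1 + eff$fano_change_pc / 100)
  rates_post <- rates * (1 + eff$baseline_gain_pc / 100)
  lam_ind_post <- pmax(rates_post - q_post * mother_rate, 0)
  v_post <- v_from_ff(ff_post, rates_post, lam_ind_post)

  # response bumps: smoothed peak = rate + atten * A, so the injected peak
  # change is expressed through the smoothing attenuation
  atten <- spec$bump_sigma_ms / sqrt(spec$bump_sigma_ms^2 + 20^2)
  A_pre <- ifelse(resp_pre, (spec$response_gain - 1) * rates, 0)
  peak_pre <- rates + atten * A_pre
  peak_post_target <- peak_pre * (1 + eff$peak_gain_pc / 100)
  A_post <- ifelse(resp_post,
                   pmax((peak_post_target - rates_post) / atten,
                        (spec$response_gain - 1) * rates_post *
                          as.numeric(!resp_pre)), 0)

  bounds <- cumsum(c(0, durations_s))
  unit_tbl <- data.frame(unit_id = seq_len(n), rate_hz = rates,
                         latency_ms = lat)

  touches_pre <- make_experimental_touch_schedule(durations_s[1],
                                                  spec$touch_rate_hz,
                                                  seed = seed + 11L)
  touches_post <- make_experimental_touch_schedule(durations_s[3],
                                                   spec$touch_rate_hz,
                                                   seed = seed + 13L)

  pre <- synth_phase(spec, unit_tbl, durations_s[1], touches_pre,
                     q_pre, v_pre, A_pre, mother_rate)
  unit_tbl_post <- unit_tbl
  unit_tbl_post$rate_hz <- rates_post
  post <- synth_phase(spec, unit_tbl_post, durations_s[3], touches_post,
                      q_post, v_post, A_post, mother_rate)
  post$time_s <- post$time_s + bounds[3]

  cond <- NULL
  if (conditioning_spikes && durations_s[2] > 0) {
    cond <- do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(unit_id = i,
                 time_s = rpois_train(rates[i], durations_s[2]) + bounds[2])
    }))
  }
  spikes <- rbind(pre, cond, post)

  phases <- data.frame(label = c("tactile_pre", "conditioning", "tactile_post"),
                       start_s = bounds[1:3], end_s = bounds[2:4],
                       stringsAsFactors = FALSE)
  events <- rbind(
    event_df(touches_pre, "touch"),
    event_df(touches_post + bounds[3], "touch"),
    event_df(phases$start_s, "phase_boundary", phases$label))

  meta <- list(seed = seed, mode = "synthetic", phases = phases,
               units = seq_len(n), reference_unit = ref_unit,
               ground_truth = list(spec = spec, categories = categories,
                                   rates_hz = rates, latency_ms = lat,
                                   q_pre = q_pre, q_post = q_post,
                                   peak_pre = peak_pre,
                                   peak_post = peak_post_target))
  session_recording(spikes, events, meta)
}
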
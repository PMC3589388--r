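#' Fixed-step reference simulator
#'
#' A deliberately simple fixed-timestep integrator for small circuits,
#' implementing the same membrane rules as the event-driven engine
#' (per-channel exponential decay, threshold + blockade + refractoriness,
#' additive STDP) by stepwise decay multiplication rather than closed-form
#' inter-event updates.  It serves as an independent cross-check: on small
#' circuits the event-driven engine must reproduce its spike times to
#' within one step.
#'
#' Within a step, events are applied in true time order (external inputs
#' before deliveries on ties) with a firing check after each, matching
#' the engine's tie-breaking.  Inputs arriving during the absolute
#' refractory period are shunted (no membrane contribution), as in the
#' event-driven engine.
#'
#' @param cell_params list as from [default_cell_params()] (shared by all
#'   neurons) or a list of such lists, one per neuron.
#' @param n_neurons number of neurons.
#' @param synapses data.frame with columns `pre`, `post`, `channel`,
#'   `weight`, `weight_baseline`, `delay`, `plastic` (may have 0 rows).
#' @param inputs data.frame of external events: `time_ms`, `neuron`,
#'   `weight` (applied on the AMPA channel).
#' @param duration_ms simulated time.
#' @param dt_ms step size (default 0.01 ms).
#' @param stdp list with `increment_frac`, `window_ms`, `wmax_factor`.
#' @return list with `spikes` (data.frame `unit_id`, `t_ms`) and `weights`
#'   (final synaptic weights).
#' @export
simulate_fixed_step <- function(cell_params, n_neurons, synapses, inputs,
                                duration_ms, dt_ms = 0.01,
                                stdp = list(increment_frac = 0, window_ms = 10,
                                            wmax_factor = 5)) {
  if (!is.null(cell_params$tau_receptor))
    cell_params <- rep(list(cell_params), n_neurons)
  taus <- t(vapply(cell_params, function(p) p$tau_receptor[CHANNELS],
                   numeric(3)))
  revs <- t(vapply(cell_params, function(p) p$reversal[CHANNELS], numeric(3)))
  vth <- vapply(cell_params, `[[`, numeric(1), "v_threshold")
  vblock <- vapply(cell_params, `[[`, numeric(1), "v_block")
  refrac <- vapply(cell_params, `[[`, numeric(1), "refrac_abs")
  Rr <- vapply(cell_params, `[[`, numeric(1), "refrac_R")
  tauR <- vapply(cell_params, `[[`, numeric(1), "tau_R")
  Hh <- vapply(cell_params, `[[`, numeric(1), "refrac_H")
  tauH <- vapply(cell_params, `[[`, numeric(1), "tau_H")

  dec_g <- exp(-dt_ms / taus)                 # n x 3 per-step decay factors
  dec_H <- exp(-dt_ms / tauH)
  dec_R <- exp(-dt_ms / tauR)

  g <- matrix(0, n_neurons, 3)
  hyper <- numeric(n_neurons)
  throff <- numeric(n_neurons)
  last_spike <- rep(-Inf, n_neurons)

  n_syn <- nrow(synapses)
  w <- synapses$weight
  eps <- stdp$increment_frac * synapses$weight_baseline
  wmax <- stdp$wmax_factor * synapses$weight_baseline
  chan <- match(synapses$channel, CHANNELS)
  last_arr <- rep(-Inf, n_syn)

  pend_t <- numeric(0); pend_s <- integer(0)  # scheduled deliveries
  spk_id <- integer(0); spk_t <- numeric(0)

  n_steps <- ceiling(duration_ms / dt_ms)
  in_step <- ceiling(inputs$time_ms / dt_ms)  # event applied at grid point >= t
  in_step[in_step == 0] <- 1

  # fire one neuron: spike bookkeeping, STDP potentiation, refractory state
  fire <- function(nn, t) {
    spk_id <<- c(spk_id, nn); spk_t <<- c(spk_t, t)
    if (n_syn) {
      pot <- which(synapses$plastic & synapses$post == nn &
                     t - last_arr >= 0 & t - last_arr <= stdp$window_ms)
      w[pot] <<- pmin(w[pot] + eps[pot], wmax[pot])
    }
    last_spike[nn] <<- t
    throff[nn] <<- throff[nn] + Rr[nn]
    hyper[nn] <<- hyper[nn] - Hh[nn]
    g[nn, ] <<- 0
    out <- which(synapses$pre == nn)
    if (length(out)) {
      pend_t <<- c(pend_t, t + synapses$delay[out])
      pend_s <<- c(pend_s, out)
    }
  }
  check <- function(nn, t) {
    V <- sum(g[nn, ]) + hyper[nn]
    if (V >= vth[nn] + throff[nn] && V < vblock[nn] &&
        t - last_spike[nn] > refrac[nn]) fire(nn, t)
  }

  for (k in seq_len(n_steps)) {
    t <- k * dt_ms
    g <- g * dec_g
    hyper <- hyper * dec_H
    throff <- throff * dec_R

    # events falling in this step, applied in true time order (external
    # inputs before deliveries on ties), each followed by a firing check
    ii <- which(in_step == k)
    due <- which(pend_t <= t)
    evs <- rbind(
      if (length(ii)) data.frame(tt = inputs$time_ms[ii], type = 0L, idx = ii),
      if (length(due)) data.frame(tt = pend_t[due], type = 3L,
                                  idx = pend_s[due]))
    if (length(due)) { pend_t <- pend_t[-due]; pend_s <- pend_s[-due] }
    if (!is.null(evs) && nrow(evs)) {
      evs <- evs[order(evs$tt, evs$type, evs$idx), , drop = FALSE]
      for (r in seq_len(nrow(evs))) {
        if (evs$type[r] == 0L) {
          j <- evs$idx[r]
          nn <- inputs$neuron[j]
          if (t - last_spike[nn] <= refrac[nn]) next   # shunted
          g[nn, 1] <- g[nn, 1] + inputs$weight[j] * revs[nn, 1]
        } else {
          s <- evs$idx[r]
          nn <- synapses$post[s]
          if (synapses$plastic[s]) {
            dts <- t - last_spike[nn]
            if (dts > 0 && dts <= stdp$window_ms)
              w[s] <- max(w[s] - eps[s], 0)
            last_arr[s] <- t
          }
          if (t - last_spike[nn] <= refrac[nn]) next   # shunted
          g[nn, chan[s]] <- g[nn, chan[s]] + w[s] * revs[nn, chan[s]]
        }
        check(nn, t)
      }
    }
  }
  list(spikes = data.frame(unit_id = spk_id, t_ms = spk_t), weights = w)
}
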
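# shared fixtures built in code

# cell with relative refractoriness disabled, so that threshold crossings
# coincide with input events (the regime where the event-driven engine and
# the fixed-step reference integrator must agree exactly)
oracle_cell <- function(...) {
  p <- default_cell_params("pyr")
  p$refrac_R <- 0
  p$refrac_H <- 0
  mods <- list(...)
  p[names(mods)] <- mods
  p
}

make_synapses <- function(pre = integer(0), post = integer(0),
                          weight = numeric(0), delay = numeric(0),
                          channel = "AMPA", plastic = FALSE) {
  n <- length(pre)
  data.frame(pre = pre, post = post,
             channel = rep_len(channel, n),
             weight = weight, weight_baseline = weight,
             delay = delay, plastic = rep_len(plastic, n))
}

make_inputs <- function(time_ms, neuron, weight) {
  data.frame(time_ms = time_ms, neuron = neuron,
             weight = rep_len(weight, length(time_ms)))
}

# small network configuration used by simulator tests (cheap to build/run)
small_config <- function(...) {
  default_model_config(scale = 1, overrides = list(...))
}

# a quick synthetic session for analysis tests
quick_session <- function(seed = 1, n_units = 20, durations = c(120, 0, 120),
                          ...) {
  generate_session(ensemble_spec(n_units = n_units, ...),
                   durations_s = durations, seed = seed,
                   conditioning_spikes = FALSE)
}
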
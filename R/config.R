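#' Default population table
#'
#' Fourteen populations: two thalamic (excitatory relay cells and the
#' inhibitory reticular shell) and, for each of cortical layers 2/3, 4, 5
#' and 6, pyramidal cells plus fast-spiking (FS) and low-threshold-spiking
#' (LTS) interneurons.  Per-population counts are expressed per 495 cells;
#' the network size is always an integer multiple of 495 so that population
#' proportions are preserved exactly at every scale.
#'
#' @return data.frame with columns `name`, `layer`, `excitatory`,
#'   `count_per_495`, `cell_class`.
#' @export
default_populations <- function() {
  data.frame(
    name = c("relay", "reticular",
             "L2/3_pyr", "L2/3_fs", "L2/3_lts",
             "L4_pyr",   "L4_fs",   "L4_lts",
             "L5_pyr",   "L5_fs",   "L5_lts",
             "L6_pyr",   "L6_fs",   "L6_lts"),
    layer = c("thalamus", "thalamus",
              "L2/3", "L2/3", "L2/3",
              "L4", "L4", "L4",
              "L5", "L5", "L5",
              "L6", "L6", "L6"),
    excitatory = c(TRUE, FALSE,
                   TRUE, FALSE, FALSE,
                   TRUE, FALSE, FALSE,
                   TRUE, FALSE, FALSE,
                   TRUE, FALSE, FALSE),
    count_per_495 = c(60L, 30L,
                      103L, 20L, 15L,
                      70L, 15L, 10L,
                      80L, 15L, 10L,
                      52L, 10L, 5L),
    cell_class = c("relay", "reticular",
                   "pyr", "fs", "lts",
                   "pyr", "fs", "lts",
                   "pyr", "fs", "lts",
                   "pyr", "fs", "lts"),
    stringsAsFactors = FALSE
  )
}

#' Default cell parameters per cell class
#'
#' Rule-based integrate-and-fire cells carry a single membrane-voltage state
#' (mV relative to rest).  Synaptic events add per-channel contributions
#' that decay with the receptor time constant; firing requires the voltage
#' to exceed a (dynamically elevated) threshold while remaining below the
#' depolarization-blockade voltage.  After a spike the threshold is raised
#' by `refrac_R` (decaying with `tau_R`) and the membrane is hyperpolarized
#' by `refrac_H` (decaying with `tau_H`); no spike can occur within
#' `refrac_abs` of the previous one.
#'
#' @param class one of "pyr", "fs", "lts", "relay", "reticular".
#' @return list of cell parameters (times in ms, voltages in mV).
#' @export
default_cell_params <- function(class = c("pyr", "fs", "lts", "relay", "reticular")) {
  class <- match.arg(class)
  base <- list(
    tau_receptor = c(AMPA = 5, NMDA = 100, GABA_A = 10),
    reversal     = c(AMPA = 65, NMDA = 90, GABA_A = -15),
    v_threshold  = 15,
    v_block      = 50,
    refrac_abs   = 2.5,
    refrac_R     = 4,
    tau_R        = 20,
    refrac_H     = 4,
    tau_H        = 30
  )
  mods <- switch(class,
    pyr       = list(),
    fs        = list(refrac_abs = 1.5, refrac_R = 1.5, tau_R = 10,
                     refrac_H = 2, tau_H = 10),
    lts       = list(refrac_abs = 2.0, v_threshold = 12),
    relay     = list(refrac_abs = 2.0),
    reticular = list(refrac_abs = 1.5, v_threshold = 12)
  )
  base[names(mods)] <- mods
  base
}

validate_cell_params <- function(p, name = "cell_params") {
  stopifnot(all(p$tau_receptor > 0), p$tau_R > 0, p$tau_H > 0)
  if (p$v_block <= p$v_threshold)
    sp_stop(sprintf("%s: v_block must exceed v_threshold", name),
            "stimplast_config_error")
  if (p$refrac_abs < 0)
    sp_stop(sprintf("%s: refrac_abs must be >= 0", name),
            "stimplast_config_error")
  if (!(p$reversal[["GABA_A"]] < 0 && p$reversal[["AMPA"]] > 0))
    sp_stop(sprintf("%s: reversal potentials must hyperpolarize for GABA_A and depolarize for AMPA", name),
            "stimplast_config_error")
  invisible(TRUE)
}

# Connectivity rule helper
conn_rule <- function(pre, post, channel, p_max, falloff, w, delay = 1,
                      plastic = NA) {
  data.frame(pre_pop = pre, post_pop = post, channel = channel,
             p_max = p_max, falloff_um = falloff, init_weight = w,
             base_delay_ms = delay, plastic = plastic,
             stringsAsFactors = FALSE)
}

#' Default connectivity rules
#'
#' Distance-dependent connection probabilities
#' `p(d) = p_max * exp(-d / falloff)` with the canonical thalamocortical
#' routing: relay -> L4 (and weakly L6), L4 -> L2/3 -> L5 -> L6 -> thalamus,
#' recurrent excitation and feedforward/feedback inhibition within each
#' layer, and the intrathalamic relay/reticular loop.  Weights are
#' dimensionless scales on the channel reversal potential (a unitary event
#' moves the membrane by `weight * reversal` mV).  Plasticity defaults to
#' excitatory synapses with cortical postsynaptic targets.
#'
#' @return data.frame of connection rules.
#' @export
default_connectivity <- function() {
  rules <- list()
  # intralaminar, per cortical layer: local excitation + inhibition
  for (L in c("L2/3", "L4", "L5", "L6")) {
    pyr <- paste0(L, "_pyr"); fs <- paste0(L, "_fs"); lts <- paste0(L, "_lts")
    rules[[length(rules) + 1]] <- rbind(
      conn_rule(pyr, pyr, "AMPA",   0.5,  100, 0.030),
      conn_rule(pyr, fs,  "AMPA",   0.6,  100, 0.030),
      conn_rule(pyr, lts, "AMPA",   0.4,  100, 0.025),
      conn_rule(fs,  pyr, "GABA_A", 0.6,  100, 0.40),
      conn_rule(fs,  fs,  "GABA_A", 0.4,  100, 0.25),
      conn_rule(lts, pyr, "GABA_A", 0.4,  150, 0.30)
    )
  }
  rules[[length(rules) + 1]] <- rbind(
    # interlaminar feedforward chain (broader spatial spread)
    conn_rule("L4_pyr",   "L2/3_pyr", "AMPA", 0.35, 300, 0.023),
    conn_rule("L4_pyr",   "L2/3_fs",  "AMPA", 0.25, 300, 0.025),
    conn_rule("L2/3_pyr", "L5_pyr",   "AMPA", 0.35, 300, 0.023),
    conn_rule("L2/3_pyr", "L5_fs",    "AMPA", 0.20, 300, 0.025),
    conn_rule("L5_pyr",   "L6_pyr",   "AMPA", 0.25, 300, 0.021),
    conn_rule("L5_pyr",   "L2/3_pyr", "AMPA", 0.10, 300, 0.015),
    conn_rule("L6_pyr",   "L4_pyr",   "AMPA", 0.10, 300, 0.020),
    # thalamocortical afferents
    conn_rule("relay", "L4_pyr", "AMPA", 0.80, 300, 0.052),
    conn_rule("relay", "L4_fs",  "AMPA", 0.55, 300, 0.033),
    conn_rule("relay", "L6_pyr", "AMPA", 0.30, 300, 0.023),
    # corticothalamic feedback
    conn_rule("L6_pyr", "relay",     "AMPA", 0.10, 300, 0.020),
    conn_rule("L6_pyr", "reticular", "AMPA", 0.15, 300, 0.025),
    # intrathalamic loop
    conn_rule("relay",     "reticular", "AMPA",   0.25, 200, 0.060),
    conn_rule("reticular", "relay",     "GABA_A", 0.25, 200, 0.30),
    conn_rule("reticular", "reticular", "GABA_A", 0.15, 200, 0.20)
  )
  do.call(rbind, rules)
}

#' Default model configuration
#'
#' Assembles the full simulation configuration: population table, cell
#' parameters, connectivity rules, sheet geometry, background drive, STDP
#' settings and stimulation strengths.  All values can be overridden by
#' passing a named list of replacements.
#'
#' @param scale network size in multiples of 495 neurons (4 gives the
#'   default 1980-cell network).
#' @param overrides named list merged (shallowly) over the defaults.
#' @return list of class `tc_config`.
#' @export
default_model_config <- function(scale = 4, overrides = list()) {
  cfg <- list(
    scale = scale,
    sheet_extent_um = 1000,
    populations = default_populations(),
    cell_params = lapply(
      setNames(nm = c("pyr", "fs", "lts", "relay", "reticular")),
      default_cell_params),
    connectivity = default_connectivity(),
    nmda_ratio = 0.15,            # NMDA co-synapse weight as fraction of AMPA
    conduction_velocity_um_ms = 1000,
    background = list(rate_hz = 145, weight = 0.06,
                      shared_rate_hz = 4, shared_weight = 0.045),
    stdp = list(increment_frac = 0.012, window_ms = 10, wmax_factor = 5,
                active_phase = "conditioning"),
    stim = list(touch_weight = 0.45, microstim_weight = 0.45,
                touch_fraction = 0.25, microstim_fraction = 0.10,
                trigger_delay_ms = 5, trigger_lockout_ms = 0,
                doublet_interval_ms = 3,
                touch_spread_ms = 12, touch_jitter_ms = 3)
  )
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  validate_config(cfg)
  structure(cfg, class = "tc_config")
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$scale) || length(cfg$scale) != 1 ||
      cfg$scale != round(cfg$scale) || cfg$scale < 1)
    sp_stop("scale must be a positive integer (network size multiples of 495)",
            "stimplast_config_error")
  pops <- cfg$populations
  if (nrow(pops) != 14)
    sp_stop("exactly 14 populations are required", "stimplast_config_error")
  if (sum(pops$count_per_495) != 495L)
    sp_stop(sprintf("per-495 population counts must sum to 495 (got %d)",
                    sum(pops$count_per_495)), "stimplast_config_error")
  for (nm in names(cfg$cell_params)) validate_cell_params(cfg$cell_params[[nm]], nm)
  conn <- cfg$connectivity
  stopifnot(all(conn$channel %in% CHANNELS))
  if (any(conn$p_max < 0 | conn$p_max > 1))
    sp_stop("connection p_max must lie in [0, 1]", "stimplast_config_error")
  if (any(conn$falloff_um <= 0))
    sp_stop("connection falloff must be > 0", "stimplast_config_error")
  bad <- setdiff(unique(c(conn$pre_pop, conn$post_pop)), pops$name)
  if (length(bad))
    sp_stop(paste("connectivity references unknown populations:",
                  paste(bad, collapse = ", ")), "stimplast_config_error")
  invisible(TRUE)
}

#' Read / write a model configuration as JSON
#'
#' @param path file path.
#' @rdname config_io
#' @export
read_model_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  cfg <- default_model_config(scale = raw$scale %||% 4)
  for (nm in intersect(names(raw), names(cfg))) {
    if (nm %in% c("populations", "connectivity")) {
      df <- as.data.frame(raw[[nm]], stringsAsFactors = FALSE)
      if (nm == "connectivity" && is.null(df$plastic)) df$plastic <- NA
      cfg[[nm]] <- df
    } else if (nm == "cell_params") {
      for (cl in names(raw$cell_params)) {
        p <- raw$cell_params[[cl]]
        p$tau_receptor <- channel_vec(p$tau_receptor)
        p$reversal <- channel_vec(p$reversal)
        cfg$cell_params[[cl]] <- p
      }
    } else cfg[[nm]] <- if (is.list(raw[[nm]])) raw[[nm]] else raw[[nm]]
  }
  validate_config(cfg)
  structure(cfg, class = "tc_config")
}

#' @param cfg a `tc_config`.
#' @rdname config_io
#' @export
write_model_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce a parsed per-channel value (named or positional) to the canonical
# channel order
channel_vec <- function(x) {
  x <- unlist(x)
  if (!is.null(names(x)) && all(CHANNELS %in% names(x))) x <- x[CHANNELS]
  stats::setNames(as.numeric(x), CHANNELS)
}

# stable md5 of a config (used for provenance in session metadata)
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_model_config(cfg, tf)
  unname(tools::md5sum(tf))
}
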
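#' Euclidean distance between positions on the cortical sheet
#'
#' @param a,b numeric length-2 vectors or two-column matrices of (x, y)
#'   positions in micrometres.
#' @return distance(s) in micrometres.
#' @export
euclidean_distance <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 2)
  if (is.null(dim(b))) b <- matrix(b, ncol = 2)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    sp_stop("positions must be finite", "stimplast_argument_error")
  sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
}

#' Distance-dependent connection probability
#'
#' `p(d) = p_max * exp(-d / falloff)`: the maximum probability at zero
#' separation decaying with a spatial length constant.
#'
#' @param d distance(s) in micrometres, `>= 0`.
#' @param p_max maximum connection probability at zero distance.
#' @param falloff length constant of the decay (micrometres).
#' @return probability in `[0, 1]`, vectorized over `d`.
#' @export
connection_probability <- function(d, p_max, falloff) {
  if (any(d < 0)) sp_stop("distance must be non-negative",
                          "stimplast_argument_error")
  stopifnot(p_max >= 0, p_max <= 1, falloff > 0)
  p_max * exp(-d / falloff)
}

#' Build a thalamocortical network
#'
#' Instantiates neurons for each population (counts scaled from the per-495
#' table), places them uniformly at random on a square sheet per layer, and
#' draws synapses according to the distance-dependent connection rules.
#' Excitatory rules on the AMPA channel also create a slower NMDA
#' co-synapse carrying `nmda_ratio` of the AMPA weight.  Structure is fully
#' determined by `(config, seed)`.
#'
#' @param config a `tc_config`, see [default_model_config()].
#' @param seed integer RNG seed for positions and connectivity.
#' @return object of class `tc_network`: list with `neurons` (id, pop,
#'   excitatory, x, y), `synapses` (pre, post, channel, weight,
#'   weight_baseline, delay, plastic), `populations`, `config`, `seed`.
#' @export
build_network <- function(config = default_model_config(), seed = 1) {
  validate_config(config)
  pops <- config$populations
  n_per_pop <- pops$count_per_495 * config$scale
  n_total <- sum(n_per_pop)

  old <- set.seed_scoped(seed)
  on.exit(restore_seed(old), add = TRUE)

  ext <- config$sheet_extent_um
  neurons <- data.frame(
    id = seq_len(n_total),
    pop = rep(pops$name, n_per_pop),
    excitatory = rep(pops$excitatory, n_per_pop),
    x = runif(n_total, 0, ext),
    y = runif(n_total, 0, ext),
    stringsAsFactors = FALSE
  )

  ids_by_pop <- split(neurons$id, factor(neurons$pop, levels = pops$name))
  conn <- config$connectivity
  vel <- config$conduction_velocity_um_ms

  syn_list <- vector("list", nrow(conn))
  for (k in seq_len(nrow(conn))) {
    rule <- conn[k, ]
    pre_ids <- ids_by_pop[[rule$pre_pop]]
    post_ids <- ids_by_pop[[rule$post_pop]]
    if (!length(pre_ids) || !length(post_ids) || rule$p_max == 0) next
    # all candidate ordered pairs, self-connections excluded
    pre_rep <- rep(pre_ids, each = length(post_ids))
    post_rep <- rep(post_ids, times = length(pre_ids))
    keep <- pre_rep != post_rep
    pre_rep <- pre_rep[keep]; post_rep <- post_rep[keep]
    d <- euclidean_distance(cbind(neurons$x[pre_rep], neurons$y[pre_rep]),
                            cbind(neurons$x[post_rep], neurons$y[post_rep]))
    # density normalized by scale: expected in-degree (and hence synaptic
    # drive per cell) is independent of network size
    p <- connection_probability(d, rule$p_max, rule$falloff_um) / config$scale
    sel <- runif(length(p)) < p
    if (!any(sel)) next
    plastic <- rule$plastic
    if (is.na(plastic)) {
      # default: excitatory synapses onto cortical excitatory targets
      # (STDP of excitatory-to-pyramidal contacts; inhibitory-target and
      # thalamic-target contacts are static)
      ip <- match(rule$post_pop, pops$name)
      plastic <- rule$channel %in% c("AMPA", "NMDA") &&
        pops$layer[ip] != "thalamus" && pops$excitatory[ip]
    }
    syn_list[[k]] <- data.frame(
      pre = pre_rep[sel], post = post_rep[sel],
      channel = rule$channel,
      weight = rule$init_weight,
      delay = rule$base_delay_ms + d[sel] / vel,
      plastic = plastic,
      stringsAsFactors = FALSE
    )
  }
  synapses <- do.call(rbind, syn_list[!vapply(syn_list, is.null, logical(1))])
  if (is.null(synapses))
    synapses <- data.frame(pre = integer(), post = integer(),
                           channel = character(), weight = numeric(),
                           delay = numeric(), plastic = logical())

  # NMDA co-synapses mirror each AMPA synapse at a fraction of its weight
  if (config$nmda_ratio > 0 && nrow(synapses)) {
    ampa <- synapses[synapses$channel == "AMPA", , drop = FALSE]
    if (nrow(ampa)) {
      nmda <- ampa
      nmda$channel <- "NMDA"
      nmda$weight <- ampa$weight * config$nmda_ratio
      synapses <- rbind(synapses, nmda)
    }
  }
  synapses$weight_baseline <- synapses$weight
  synapses <- synapses[order(synapses$pre, synapses$post, synapses$channel), ]
  rownames(synapses) <- NULL

  structure(list(neurons = neurons, synapses = synapses,
                 populations = pops, config = config, seed = seed),
            class = "tc_network")
}

# scoped RNG helpers: preserve the caller's RNG state
set.seed_scoped <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.tc_network <- function(x, ...) {
  cat(sprintf("<tc_network> %d neurons (%d populations), %d synapses, seed %d\n",
              nrow(x$neurons), nrow(x$populations), nrow(x$synapses), x$seed))
  tab <- table(factor(x$neurons$pop, levels = x$populations$name))
  cat(paste(sprintf("  %-10s %4d", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  invisible(x)
}

# neuron ids of a population (helper used by protocols)
pop_ids <- function(network, pop) {
  network$neurons$id[network$neurons$pop == pop]
}

# cortical units: everything outside the thalamus, the analysis ensemble
#' Identifiers of cortical neurons (the analyzed ensemble)
#' @param network a `tc_network`.
#' @export
cortical_ids <- function(network) {
  thal <- network$populations$name[network$populations$layer == "thalamus"]
  network$neurons$id[!(network$neurons$pop %in% thal)]
}
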
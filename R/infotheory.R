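#' Bin spike counts over a phase
#'
#' @param recording a `session_recording`.
#' @param phase phase label.
#' @param bin_ms bin width (default 10 ms; at ~10 Hz most bins hold 0 or 1
#'   spikes).
#' @param units unit ids (default: analyzed ensemble).
#' @return object of class `binned_counts`: integer matrix `counts`
#'   (units x bins, rownames = unit ids) and `bin_ms`.
#' @export
bin_spike_counts <- function(recording, phase, bin_ms = 10,
                             units = analysis_units(recording)) {
  win <- phase_window(recording, phase)
  n_bins <- floor((win[2] - win[1]) * 1000 / bin_ms)
  if (n_bins < 1)
    sp_stop("phase too short for the requested bin width",
            "stimplast_argument_error")
  trains <- phase_spikes(recording, phase, units)
  m <- vapply(trains, function(tr) {
    rel <- (tr - win[1]) * 1000
    idx <- floor(rel / bin_ms) + 1
    tabulate(idx[idx >= 1 & idx <= n_bins], nbins = n_bins)
  }, integer(n_bins))
  counts <- if (n_bins == 1) matrix(as.integer(m), ncol = 1) else t(m)
  rownames(counts) <- units
  structure(list(counts = counts, bin_ms = bin_ms, units = units),
            class = "binned_counts")
}

# entropy (bits) of integer codes
code_entropy <- function(codes) {
  p <- tabulate(codes)
  p <- p[p > 0] / length(codes)
  -sum(p * log2(p))
}

# rows of a discrete matrix -> integer joint codes (mixed radix)
joint_codes <- function(M) {
  k <- nrow(M)
  codes <- rep(1L, ncol(M))
  radix <- 1
  for (i in seq_len(k)) {
    vals <- match(M[i, ], sort(unique(M[i, ])))
    codes <- codes + (vals - 1L) * radix
    radix <- radix * length(unique(M[i, ]))
  }
  codes
}

#' Plug-in mutual information of two count sequences
#'
#' `I(X;Y) = sum p(x,y) log2 p(x,y) / (p(x) p(y))` over the empirical
#' joint distribution.  Symmetric and bounded by `min(H(X), H(Y))`.
#'
#' @param x,y equal-length discrete (count) sequences.
#' @return mutual information in bits.
#' @export
plugin_mi <- function(x, y) {
  if (length(x) != length(y))
    sp_stop("x and y must have equal length", "stimplast_argument_error")
  hx <- code_entropy(match(x, sort(unique(x))))
  hy <- code_entropy(match(y, sort(unique(y))))
  hxy <- code_entropy(joint_codes(rbind(x, y)))
  hx + hy - hxy
}

# total correlation (multi-information) of the rows of M, in bits
plugin_total_correlation <- function(M) {
  hs <- apply(M, 1, function(r) code_entropy(match(r, sort(unique(r)))))
  sum(hs) - code_entropy(joint_codes(M))
}

# shuffle-corrected total correlation: subtract the mean over shuffles in
# which every row is independently bin-permuted (marginals preserved, all
# dependence destroyed)
shuffle_corrected_tc <- function(M, n_shuffles = 20, seed = 1) {
  if (n_shuffles < 1)
    sp_stop("n_shuffles must be >= 1", "stimplast_argument_error")
  raw <- plugin_total_correlation(M)
  n <- ncol(M)
  old <- set.seed_scoped(seed)
  on.exit(restore_seed(old))
  sh <- vapply(seq_len(n_shuffles), function(s) {
    Ms <- M
    for (i in seq_len(nrow(M))) Ms[i, ] <- Ms[i, sample.int(n)]
    plugin_total_correlation(Ms)
  }, numeric(1))
  raw - mean(sh)
}

#' Shuffle-corrected mutual information
#'
#' Plug-in MI minus the mean MI of surrogates in which each sequence's
#' bins are independently permuted, removing the small-sample positive
#' bias.  The corrected value may be slightly negative.
#'
#' @inheritParams plugin_mi
#' @param n_shuffles number of permutation surrogates.
#' @param seed RNG seed.
#' @return bias-corrected mutual information in bits.
#' @export
shuffle_corrected_mi <- function(x, y, n_shuffles = 20, seed = 1) {
  if (length(x) != length(y))
    sp_stop("x and y must have equal length", "stimplast_argument_error")
  shuffle_corrected_tc(rbind(x, y), n_shuffles, seed)
}

# vectorized MI (bits) for all pairs of binary rows from co-occurrence counts
binary_pair_mi <- function(n11, r, N) {
  n10 <- outer(r, rep(1, length(r))) - n11
  n01 <- t(n10)
  n00 <- N - n11 - n10 - n01
  px1 <- r / N
  plogp <- function(nn, pp) {
    out <- nn / N * log2(pmax(nn / N, 1e-300) / pmax(pp, 1e-300))
    out[nn == 0] <- 0
    out
  }
  pj <- function(pi_, pj_) outer(pi_, pj_)
  plogp(n11, pj(px1, px1)) + plogp(n10, pj(px1, 1 - px1)) +
    plogp(n01, pj(1 - px1, px1)) + plogp(n00, pj(1 - px1, 1 - px1))
}

#' Shuffle-corrected MI matrix over all unit pairs
#'
#' Counts are binarized (any spike in a bin) for joint-distribution
#' estimation; the bias term is the mean over shuffles in which every
#' unit's bin sequence is independently permuted.  The matrix is symmetric
#' with an undefined (NA) diagonal.
#'
#' @param counts a `binned_counts`.
#' @param n_shuffles permutation surrogates per pair.
#' @param seed RNG seed.
#' @return object of class `info_result`: `mi_matrix` (bits), `units`,
#'   `n_shuffles`.
#' @export
mi_matrix <- function(counts, n_shuffles = 20, seed = 1) {
  B <- (counts$counts > 0) * 1
  if (nrow(B) < 2)
    sp_stop("at least two units are required", "stimplast_argument_error")
  N <- ncol(B)
  r <- rowSums(B)
  raw <- binary_pair_mi(tcrossprod(B), r, N)
  old <- set.seed_scoped(seed)
  on.exit(restore_seed(old))
  bias <- 0
  for (s in seq_len(n_shuffles)) {
    Bs <- B
    for (i in seq_len(nrow(B))) Bs[i, ] <- Bs[i, sample.int(N)]
    bias <- bias + binary_pair_mi(tcrossprod(Bs), r, N)
  }
  mi <- raw - bias / n_shuffles
  diag(mi) <- NA_real_
  dimnames(mi) <- list(counts$units, counts$units)
  structure(list(mi_matrix = mi, units = counts$units,
                 n_shuffles = n_shuffles, seed = seed),
            class = "info_result")
}

#' Ensemble multi-information via random sub-ensembles
#'
#' The exact joint distribution over a full ~40-unit ensemble is not
#' estimable, so the total correlation
#' `sum_i H(X_i) - H(X_1, ..., X_k)` is computed on binarized counts for
#' random sub-ensembles of `subensemble_size` units and averaged; each
#' sub-ensemble value is shuffle-corrected.  At `subensemble_size = 2`
#' this reduces to pairwise mutual information.
#'
#' @param counts a `binned_counts`.
#' @param subensemble_size units per sub-ensemble (>= 2).
#' @param n_subensembles random sub-ensembles to average.
#' @param n_shuffles permutation surrogates per sub-ensemble.
#' @param seed RNG seed.
#' @return list: `multi_info_bits` (mean), `per_subensemble`, `members`.
#' @export
multi_information <- function(counts, subensemble_size = 5,
                              n_subensembles = 50, n_shuffles = 20,
                              seed = 1) {
  B <- (counts$counts > 0) * 1L
  k <- subensemble_size
  if (k < 2)
    sp_stop("subensemble_size must be >= 2", "stimplast_argument_error")
  if (k > nrow(B))
    sp_stop("subensemble_size exceeds the number of units",
            "stimplast_argument_error")
  old <- set.seed_scoped(seed)
  members <- lapply(seq_len(n_subensembles), function(j)
    sort(sample.int(nrow(B), k)))
  restore_seed(old)
  vals <- vapply(seq_along(members), function(j) {
    shuffle_corrected_tc(B[members[[j]], , drop = FALSE], n_shuffles,
                         seed = seed + j)
  }, numeric(1))
  list(multi_info_bits = mean(vals), per_subensemble = vals,
       members = members)
}

#' Pairwise MI as a function of inter-unit distance
#'
#' @param info an `info_result`.
#' @param positions data.frame `id`, `x`, `y` (micrometres) covering all
#'   units.
#' @param breaks_um distance bin edges for the binned mean curve.
#' @return list: `pairs` (data.frame `unit_a`, `unit_b`, `mi_bits`,
#'   `distance_um`) and `binned` (distance bin centre, mean MI, n pairs).
#' @export
mi_vs_distance <- function(info, positions,
                           breaks_um = seq(0, 1500, by = 100)) {
  units <- as.integer(info$units)
  idx <- match(units, positions$id)
  if (anyNA(idx))
    sp_stop("positions missing for some units", "stimplast_argument_error")
  xy <- cbind(positions$x[idx], positions$y[idx])
  n <- length(units)
  ij <- which(upper.tri(info$mi_matrix), arr.ind = TRUE)
  d <- euclidean_distance(xy[ij[, 1], , drop = FALSE],
                          xy[ij[, 2], , drop = FALSE])
  pairs <- data.frame(unit_a = units[ij[, 1]], unit_b = units[ij[, 2]],
                      mi_bits = info$mi_matrix[ij], distance_um = d)
  bin <- cut(pairs$distance_um, breaks_um, include.lowest = TRUE)
  binned <- data.frame(
    distance_um = (head(breaks_um, -1) + tail(breaks_um, -1)) / 2,
    mean_mi_bits = as.numeric(tapply(pairs$mi_bits, bin, mean)),
    n_pairs = as.integer(table(bin)))
  list(pairs = pairs, binned = binned)
}

#' Trigger-pair versus non-trigger-pair MI contrast
#'
#' Splits unit pairs by whether they contain the spike-trigger reference
#' unit and reports, for each group, the proportion of pairs whose MI
#' increased from before to after, plus the per-pair MI changes for
#' rank-based testing.
#'
#' @param info_before,info_after `info_result`s over the same units.
#' @param reference_unit the reference unit id.
#' @return list: `prop_increased_trigger`, `prop_increased_nontrigger`,
#'   `delta_trigger`, `delta_nontrigger`.
#' @export
trigger_pair_contrast <- function(info_before, info_after, reference_unit) {
  stopifnot(identical(info_before$units, info_after$units))
  units <- as.integer(info_before$units)
  if (!(reference_unit %in% units))
    sp_stop("reference unit absent from the MI matrices",
            "stimplast_argument_error")
  if (length(units) < 2)
    sp_stop("need at least two units", "stimplast_argument_error")
  ij <- which(upper.tri(info_before$mi_matrix), arr.ind = TRUE)
  delta <- info_after$mi_matrix[ij] - info_before$mi_matrix[ij]
  has_ref <- units[ij[, 1]] == reference_unit |
             units[ij[, 2]] == reference_unit
  list(prop_increased_trigger = mean(delta[has_ref] > 0),
       prop_increased_nontrigger = mean(delta[!has_ref] > 0),
       delta_trigger = delta[has_ref],
       delta_nontrigger = delta[!has_ref])
}

#' Crosscorrelogram with shuffle-based significance bounds
#'
#' Conditional rate of `y` spikes around `x` spikes in `bin_ms` lag bins
#' up to `maxlag_ms`, with pointwise 95% bounds from surrogates in which
#' `y` is circularly shifted by random offsets (rates and ISI structure
#' preserved, timing relation destroyed).
#'
#' @param x,y spike-time vectors (s), non-empty.
#' @param duration_s recording span used for normalization and shifting.
#' @param maxlag_ms,bin_ms lag range and resolution.
#' @param n_shuffles surrogate count.
#' @param seed RNG seed.
#' @return list: `lag_ms`, `rate_hz`, `lower_hz`, `upper_hz`.
#' @export
crosscorrelogram <- function(x, y, duration_s = max(c(x, y)),
                             maxlag_ms = 100, bin_ms = 1, n_shuffles = 100,
                             seed = 1) {
  if (!length(x) || !length(y))
    sp_stop("both spike trains must be non-empty", "stimplast_argument_error")
  breaks <- seq(-maxlag_ms, maxlag_ms, by = bin_ms)
  ccg_counts <- function(ys) {
    lags <- unlist(lapply(x, function(t0) {
      d <- (ys - t0) * 1000
      d[d >= -maxlag_ms & d < maxlag_ms]
    }), use.names = FALSE)
    tabulate(findInterval(lags, breaks), nbins = length(breaks) - 1)
  }
  norm <- length(x) * bin_ms / 1000          # counts -> Hz given x spikes
  obs <- ccg_counts(y) / norm
  old <- set.seed_scoped(seed)
  on.exit(restore_seed(old))
  sh <- vapply(seq_len(n_shuffles), function(s) {
    ys <- (y + runif(1, 0, duration_s)) %% duration_s
    ccg_counts(sort(ys)) / norm
  }, numeric(length(breaks) - 1))
  list(lag_ms = (head(breaks, -1) + tail(breaks, -1)) / 2,
       rate_hz = obs,
       lower_hz = apply(sh, 1, quantile, 0.025),
       upper_hz = apply(sh, 1, quantile, 0.975))
}

#' Pairwise count-correlation matrix with shuffle significance
#'
#' Pearson correlation of binned counts for all unit pairs.  Pairs
#' involving a zero-variance unit are NA.  Significance is assessed
#' against the pooled null distribution of correlations from surrogates in
#' which every unit's bins are independently permuted.
#'
#' @param counts a `binned_counts`.
#' @param n_shuffles surrogate count.
#' @param alpha two-sided significance level.
#' @param seed RNG seed.
#' @return list: `r_matrix`, `significant` (logical matrix),
#'   `null_bounds`.
#' @export
correlation_matrix <- function(counts, n_shuffles = 20, alpha = 0.05,
                               seed = 1) {
  M <- counts$counts
  if (nrow(M) < 2)
    sp_stop("at least two units are required", "stimplast_argument_error")
  v <- apply(M, 1, stats::var)
  r <- suppressWarnings(stats::cor(t(M)))
  r[v == 0, ] <- NA_real_
  r[, v == 0] <- NA_real_
  diag(r) <- NA_real_
  old <- set.seed_scoped(seed)
  on.exit(restore_seed(old))
  null_vals <- unlist(lapply(seq_len(n_shuffles), function(s) {
    Ms <- M
    for (i in seq_len(nrow(M))) Ms[i, ] <- Ms[i, sample.int(ncol(M))]
    rs <- suppressWarnings(stats::cor(t(Ms)))
    rs[upper.tri(rs)]
  }), use.names = FALSE)
  null_vals <- null_vals[is.finite(null_vals)]
  bounds <- quantile(null_vals, c(alpha / 2, 1 - alpha / 2))
  sig <- !is.na(r) & (r < bounds[1] | r > bounds[2])
  dimnames(r) <- list(counts$units, counts$units)
  list(r_matrix = r, significant = sig, null_bounds = bounds)
}
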
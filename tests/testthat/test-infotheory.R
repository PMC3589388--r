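# independent brute-force entropy oracle used by several tests
brute_entropy <- function(M) {
  patterns <- apply(M, 2, paste, collapse = ",")
  p <- table(patterns) / length(patterns)
  -sum(p * log2(p))
}
brute_mi <- function(x, y) {
  brute_entropy(rbind(x)) + brute_entropy(rbind(y)) -
    brute_entropy(rbind(x, y))
}

test_that("binned counts conserve total spikes", {
  rec <- quick_session(seed = 1, n_units = 8)
  counts <- bin_spike_counts(rec, "tactile_pre", bin_ms = 10)
  win <- rec$meta$phases
  n_in_phase <- sum(rec$spikes$time_s < win$end_s[1])
  expect_equal(sum(counts$counts), n_in_phase)
  # single-bin edge case: one column holding the per-unit totals
  win_len <- (win$end_s[1] - win$start_s[1]) * 1000
  one <- bin_spike_counts(rec, "tactile_pre", bin_ms = win_len)
  expect_equal(ncol(one$counts), 1L)
  expect_equal(as.integer(one$counts), unname(rowSums(counts$counts)))
  expect_error(bin_spike_counts(rec, "nope"), class = "stimplast_argument_error")
})

test_that("plug-in MI matches closed forms and the brute-force oracle", {
  x <- rep(c(0L, 1L), 500)
  expect_equal(plugin_mi(x, x), 1)            # fair coin with itself: 1 bit
  expect_equal(plugin_mi(x, rep(0L, 1000)), 0)
  # exact 4-cell joint: p(0,0)=p(1,1)=0.4, p(0,1)=p(1,0)=0.1 -> 0.278 bits
  xy <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))[rep(1:4, c(40, 40, 10, 10)), ]
  expect_equal(plugin_mi(xy[, 1], xy[, 2]), 0.278, tolerance = 5e-4)
  expect_equal(plugin_mi(xy[, 1], xy[, 2]), brute_mi(xy[, 1], xy[, 2]))
  expect_equal(plugin_mi(xy[, 1], xy[, 2]), plugin_mi(xy[, 2], xy[, 1]))
  expect_error(plugin_mi(1:4, 1:5), class = "stimplast_argument_error")
})

test_that("MI respects the entropy bound on random count sequences", {
  set.seed(8)
  for (rep in 1:10) {
    x <- rpois(400, 0.5); y <- rpois(400, 0.8)
    i <- plugin_mi(x, y)
    expect_gte(i, 0)
    expect_lte(i, min(brute_entropy(rbind(x)), brute_entropy(rbind(y))) + 1e-12)
  }
})

test_that("plug-in entropies match exhaustive enumeration on tiny ensembles", {
  set.seed(9)
  for (rep in 1:8) {
    k <- sample(2:3, 1)
    M <- matrix(rbinom(k * 16, 1, 0.4), nrow = k)
    expect_equal(stimplast:::plugin_total_correlation(M),
                 sum(apply(M, 1, function(r) brute_entropy(rbind(r)))) -
                   brute_entropy(M),
                 tolerance = 1e-12)
  }
})

test_that("shuffle correction removes the positive bias of independent pairs", {
  set.seed(10)
  raw <- corr <- numeric(20)
  for (s in 1:20) {
    x <- rbinom(10000, 1, 0.1); y <- rbinom(10000, 1, 0.1)
    raw[s] <- plugin_mi(x, y)
    corr[s] <- shuffle_corrected_mi(x, y, n_shuffles = 20, seed = s)
  }
  expect_gt(mean(raw), 0)                      # plug-in bias is positive
  expect_lt(abs(mean(corr)), 0.005)            # corrected ~ 0
  expect_lt(mean(abs(corr)), mean(raw))        # correction beats the bias
})

test_that("corrected MI of identical trains stays close to the entropy", {
  x <- rbinom(4000, 1, 0.5)
  ent <- brute_entropy(rbind(x))
  v <- shuffle_corrected_mi(x, x, n_shuffles = 20, seed = 1)
  expect_gt(v, 0.8 * ent)                      # correction << signal
  expect_lte(v, ent)
  expect_error(shuffle_corrected_mi(x, x, n_shuffles = 0),
               class = "stimplast_argument_error")
})

test_that("correlated pairs exceed their own shuffle distribution", {
  pair <- generate_correlated_pair(10, 0.3, 200, seed = 3)
  x <- tabulate(floor(pair[[1]] / 0.01) + 1, nbins = 20000)
  y <- tabulate(floor(pair[[2]] / 0.01) + 1, nbins = 20000)
  obs <- plugin_mi(pmin(x, 1), pmin(y, 1))
  set.seed(4)
  null <- vapply(1:99, function(s) plugin_mi(pmin(x, 1), sample(pmin(y, 1))),
                 numeric(1))
  expect_gt(obs, quantile(null, 0.99))
})

test_that("uncorrected MI grows with bin size on fixed data", {
  pair <- generate_correlated_pair(10, 0.3, 200, seed = 5)
  mi_at <- function(bin) {
    nb <- floor(200 / bin)
    x <- tabulate(floor(pair[[1]] / bin) + 1, nbins = nb)
    y <- tabulate(floor(pair[[2]] / bin) + 1, nbins = nb)
    plugin_mi(pmin(x, 1), pmin(y, 1))
  }
  vals <- vapply(c(0.002, 0.005, 0.01, 0.02), mi_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the MI matrix is symmetric and consistent with the pair routine", {
  rec <- quick_session(seed = 6, n_units = 6, pairwise_correlation = 0.1)
  counts <- bin_spike_counts(rec, "tactile_pre")
  info <- mi_matrix(counts, n_shuffles = 10, seed = 3)
  expect_true(isSymmetric(unname(info$mi_matrix)))
  expect_true(all(is.na(diag(info$mi_matrix))))
  # 2-unit case equals shuffle_corrected_mi with the same seed
  two <- counts
  two$counts <- counts$counts[1:2, , drop = FALSE]
  two$units <- counts$units[1:2]
  m2 <- mi_matrix(two, n_shuffles = 10, seed = 5)
  direct <- shuffle_corrected_mi(pmin(two$counts[1, ], 1),
                                 pmin(two$counts[2, ], 1),
                                 n_shuffles = 10, seed = 5)
  expect_equal(m2$mi_matrix[1, 2], direct, tolerance = 1e-12)
  one <- two
  one$counts <- two$counts[1, , drop = FALSE]
  one$units <- two$units[1]
  expect_error(mi_matrix(one), class = "stimplast_argument_error")
})

test_that("independent ensembles have near-zero corrected MI", {
  rec <- quick_session(seed = 7, n_units = 8, pairwise_correlation = 0,
                       responsive_fraction = 0)
  counts <- bin_spike_counts(rec, "tactile_pre")
  info <- mi_matrix(counts, n_shuffles = 20, seed = 1)
  expect_lt(abs(mean(info$mi_matrix[upper.tri(info$mi_matrix)])), 0.003)
})

test_that("multi-information reduces to pairwise MI at sub-ensemble size 2", {
  rec <- quick_session(seed = 8, n_units = 2, pairwise_correlation = 0.2)
  counts <- bin_spike_counts(rec, "tactile_pre")
  seed <- 11
  multi <- multi_information(counts, subensemble_size = 2, n_subensembles = 1,
                             n_shuffles = 10, seed = seed)
  direct <- shuffle_corrected_mi(pmin(counts$counts[1, ], 1),
                                 pmin(counts$counts[2, ], 1),
                                 n_shuffles = 10, seed = seed + 1)
  expect_equal(multi$multi_info_bits, direct, tolerance = 1e-12)
})

test_that("multi-information of dependent copies matches the closed form", {
  # three identical fair-coin trains: TC = 3 * 1 - 1 = 2 bits (plug-in)
  x <- rep(c(0L, 1L), 32)
  M <- rbind(x, x, x)
  expect_equal(stimplast:::plugin_total_correlation(M), 2)
  # independent units: multi-information ~ 0
  rec <- quick_session(seed = 9, n_units = 6, pairwise_correlation = 0,
                       responsive_fraction = 0)
  counts <- bin_spike_counts(rec, "tactile_pre")
  multi <- multi_information(counts, 3, n_subensembles = 10, n_shuffles = 10,
                             seed = 2)
  expect_lt(abs(multi$multi_info_bits), 0.01)
  expect_error(multi_information(counts, 1), class = "stimplast_argument_error")
  expect_error(multi_information(counts, 10), class = "stimplast_argument_error")
})

test_that("MI declines with distance when coupling is local", {
  # construct: three spatial pairs, correlation only within pairs
  set.seed(12)
  trains <- list()
  for (k in 1:3) {
    p <- generate_correlated_pair(10, 0.35, 120, seed = 20 + k)
    trains[[2 * k - 1]] <- p[[1]]; trains[[2 * k]] <- p[[2]]
  }
  spikes <- do.call(rbind, lapply(seq_along(trains), function(i)
    data.frame(unit_id = i, time_s = trains[[i]])))
  meta <- list(phases = data.frame(label = c("tactile_pre", "conditioning",
                                             "tactile_post"),
                                   start_s = c(0, 120, 120),
                                   end_s = c(120, 120, 120)),
               units = 1:6)
  rec <- session_recording(spikes, event_df(numeric(0), "touch"), meta)
  counts <- bin_spike_counts(rec, "tactile_pre")
  info <- mi_matrix(counts, n_shuffles = 10, seed = 1)
  # co-located pairs at < 50 um, unrelated pairs far apart
  positions <- data.frame(id = 1:6,
                          x = c(0, 30, 500, 530, 0, 30),
                          y = c(0, 0, 0, 0, 800, 800))
  mvd <- mi_vs_distance(info, positions, breaks_um = c(0, 100, 1000))
  expect_gt(mvd$binned$mean_mi_bits[1], mvd$binned$mean_mi_bits[2])
  expect_equal(nrow(mvd$pairs), 15)
  expect_error(mi_vs_distance(info, positions[-1, ]),
               class = "stimplast_argument_error")
})

test_that("trigger-pair contrast flags reference-specific potentiation", {
  rec <- generate_session(
    ensemble_spec(n_units = 14, pairwise_correlation = 0.08,
                  effect = before_after_effect(trigger_correlation_change_pc = 120)),
    durations_s = c(300, 0, 300), seed = 13, conditioning_spikes = FALSE)
  cts <- function(ph) bin_spike_counts(rec, ph)
  before <- mi_matrix(cts("tactile_pre"), n_shuffles = 10, seed = 1)
  after <- mi_matrix(cts("tactile_post"), n_shuffles = 10, seed = 1)
  tc <- trigger_pair_contrast(before, after, rec$meta$reference_unit)
  expect_gt(tc$prop_increased_trigger, tc$prop_increased_nontrigger)
  expect_length(tc$delta_trigger, 13)
  expect_length(tc$delta_nontrigger, choose(13, 2))
  expect_error(trigger_pair_contrast(before, after, 999),
               class = "stimplast_argument_error")
})

test_that("crosscorrelograms locate imposed lags and calibrate under independence", {
  set.seed(14)
  x <- sort(runif(800, 0, 100))
  ccg <- crosscorrelogram(x, x + 0.010, duration_s = 101, n_shuffles = 50,
                          seed = 1)
  expect_equal(ccg$lag_ms[which.max(ccg$rate_hz)], 10.5, tolerance = 1)
  expect_gt(max(ccg$rate_hz), max(ccg$upper_hz))
  y <- sort(runif(800, 0, 100))
  ccg0 <- crosscorrelogram(x, y, duration_s = 100, n_shuffles = 100, seed = 2)
  inside <- mean(ccg0$rate_hz >= ccg0$lower_hz & ccg0$rate_hz <= ccg0$upper_hz)
  expect_gte(inside, 0.94)
  expect_error(crosscorrelogram(numeric(0), y),
               class = "stimplast_argument_error")
})

test_that("count correlation matrices flag duplicates and degenerate units", {
  rec <- quick_session(seed = 15, n_units = 5, pairwise_correlation = 0)
  counts <- bin_spike_counts(rec, "tactile_pre")
  counts$counts <- rbind(counts$counts, counts$counts[1, ],
                         rep(0L, ncol(counts$counts)))
  counts$units <- c(counts$units, 6L, 7L)
  rownames(counts$counts) <- counts$units
  cm <- correlation_matrix(counts, n_shuffles = 10, seed = 1)
  expect_equal(cm$r_matrix["1", "6"], 1)
  expect_true(cm$significant["1", "6"])
  expect_true(all(is.na(cm$r_matrix["7", ])))
  off <- cm$r_matrix[upper.tri(cm$r_matrix)]
  expect_lt(abs(mean(off[is.finite(off)][-which.max(off[is.finite(off)])])),
            0.05)
})
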
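test_that("a stationary Poisson unit gives a flat, nonresponsive PSTH", {
  set.seed(1)
  train <- sort(runif(10 * 300, 0, 300))      # 10 Hz over 300 s
  events <- seq(2, 298, by = 1)
  psth <- compute_psth(train, events)
  expect_true(all(abs(psth$rate_hz - 10) < 3)) # ~3.5 SD of the local mean
  expect_equal(psth$baseline_mean_hz, 10, tolerance = 0.1)
  m <- response_metrics(psth)
  expect_false(m$responsive)
  expect_lt(m$auc, 0.05)
})

test_that("PSTH recovers an injected response bump latency", {
  set.seed(2)
  events <- seq(1, 199, by = 2)
  base <- sort(runif(5 * 200, 0, 200))
  bump <- unlist(lapply(events, function(e) e + rnorm(3, 0.030, 0.010)))
  psth <- compute_psth(sort(c(base, bump)), events)
  m <- response_metrics(psth)
  expect_true(m$responsive)
  expect_lt(abs(m$latency_ms - 30), 5)
  expect_gt(m$peak_rate_hz, psth$baseline_mean_hz + 3 * psth$baseline_sd_hz)
})

test_that("an empty train yields an all-zero PSTH", {
  psth <- compute_psth(numeric(0), c(1, 2, 3))
  expect_true(all(psth$rate_hz == 0))
  expect_equal(psth$baseline_sd_hz, 0)
  expect_error(compute_psth(c(1, 2), numeric(0)),
               class = "stimplast_argument_error")
})

test_that("kernel smoothing conserves spike mass away from the edges", {
  set.seed(3)
  events <- seq(2, 198, by = 2)
  train <- sort(runif(8 * 200, 0, 200))
  psth <- compute_psth(train, events, range_ms = c(-250, 300))
  # integral of rate over the range ~ mean count per trial in the range
  integral <- sum(psth$rate_hz) / 1000
  count <- mean(vapply(events, function(e)
    sum(train >= e - 0.25 & train < e + 0.3), numeric(1)))
  expect_equal(integral, count, tolerance = 0.01)
})

test_that("response metrics match hand computation on a constructed curve", {
  # triangular response: baseline 5 Hz (SD 1), peak 20 Hz at 35 ms,
  # crossings of the 8 Hz (3 SD) level 30 ms apart
  ct <- seq(-249.5, 299.5, by = 1)
  rate <- 5 + 15 * pmax(0, 1 - abs(ct - 35) / 18.75)
  psth <- structure(list(bin_centers_ms = ct, rate_hz = rate, n_trials = 100,
                         baseline_mean_hz = 5, baseline_sd_hz = 1),
                    class = "psth_result")
  m <- response_metrics(psth)
  expect_true(m$responsive)
  expect_equal(m$peak_rate_hz, max(rate[ct >= 0 & ct < 70]))
  expect_equal(m$latency_ms, 35.5, tolerance = 1)
  expect_equal(m$sharpness_hz_per_ms, 20 / 30, tolerance = 0.07)
  # area above baseline: triangle area 0.5 * base * height (in spikes)
  expect_equal(m$auc, 0.5 * 2 * 18.75 * 15 / 1000, tolerance = 0.02)
})

test_that("degenerate baselines fall back to a strict mean comparison", {
  ct <- seq(-249.5, 299.5, by = 1)
  rate <- ifelse(ct > 10 & ct < 40, 4, 0)
  psth <- structure(list(bin_centers_ms = ct, rate_hz = rate, n_trials = 10,
                         baseline_mean_hz = 0, baseline_sd_hz = 0),
                    class = "psth_result")
  m <- response_metrics(psth)
  expect_true(m$responsive)
  expect_true(m$degenerate_baseline)
})

test_that("Fano factor is 1 for Poisson, 0 for identical trains", {
  trains <- generate_poisson_trains(10, 1000, 0.5, seed = 4)
  ff <- fano_timecourse(lapply(trains, function(tr) tr * 1000),
                        range_ms = c(0, 500))
  expect_lt(abs(mean(ff$fano, na.rm = TRUE) - 1), 0.02)
  expect_true(all(abs(ff$fano - 1) < 0.35, na.rm = TRUE))
  same <- rep(list(c(10, 55, 120, 340)), 50)
  ff0 <- fano_timecourse(same, range_ms = c(0, 400))
  expect_true(all(ff0$fano[!is.na(ff0$fano)] == 0))
  expect_error(fano_timecourse(same[1]), class = "stimplast_argument_error")
})

test_that("binomial counts give Fano factor 1 - p", {
  # n Bernoulli spike slots per window at probability p
  set.seed(6)
  n <- 8; p <- 0.4
  trials <- lapply(1:4000, function(k) {
    hits <- which(runif(n) < p)
    (hits - 0.5) * (20 / n)                   # all inside one 20 ms window
  })
  ff <- fano_timecourse(trials, window_ms = 20, step_ms = 20,
                        range_ms = c(0, 20))
  expect_equal(ff$fano[1], 1 - p, tolerance = 0.03)
})

test_that("doubling trials preserves expected Fano and shrinks its spread", {
  ffs <- function(n_tr, seeds) vapply(seeds, function(s) {
    trains <- generate_poisson_trains(20, n_tr, 0.1, seed = s)
    mean(fano_timecourse(lapply(trains, `*`, 1000),
                         range_ms = c(0, 100))$fano, na.rm = TRUE)
  }, numeric(1))
  a <- ffs(100, 1:12)
  b <- ffs(400, 1:12)
  expect_equal(mean(a), mean(b), tolerance = 0.05)
  expect_lt(sd(b), sd(a))
})

test_that("responsiveness count is monotone in the SD criterion", {
  rec <- quick_session(seed = 21, n_units = 25, responsive_fraction = 0.5)
  ev <- phase_events(rec, "tactile_pre", "touch")
  trains <- phase_spikes(rec, "tactile_pre")
  n_resp <- vapply(c(2, 3, 4, 6), function(k) {
    sum(vapply(trains, function(tr)
      response_metrics(compute_psth(tr, ev), sd_criterion = k)$responsive,
      logical(1)))
  }, numeric(1))
  expect_true(all(diff(n_resp) <= 0))
})

test_that("four-way responsiveness classification sums to one", {
  rec <- quick_session(seed = 31, n_units = 30)
  pre <- phase_response_metrics(rec, "tactile_pre")
  post <- phase_response_metrics(rec, "tactile_post")
  cls <- classify_responsiveness(pre, post)
  expect_equal(sum(cls$proportions), 1)
  expect_equal(nrow(cls$labels), 30)
  # all-responsive edge case
  pre2 <- pre; pre2$responsive <- TRUE
  post2 <- post; post2$responsive <- TRUE
  expect_equal(unname(classify_responsiveness(pre2, post2)$proportions),
               c(1, 0, 0, 0))
  expect_error(classify_responsiveness(pre[-1, ], post),
               class = "stimplast_argument_error")
})

test_that("phases without touch events are rejected", {
  rec <- quick_session(seed = 41, n_units = 5)
  rec$events <- rec$events[rec$events$event_type != "touch" |
                             rec$events$time_s > rec$meta$phases$end_s[1], ]
  expect_error(phase_response_metrics(rec, "tactile_pre"),
               class = "stimplast_argument_error")
})
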
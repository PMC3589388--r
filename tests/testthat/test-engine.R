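# event-driven engine vs independent fixed-step reference, plus the
# membrane and plasticity rules on hand-built circuits

test_that("event-driven engine matches the fixed-step oracle on a chain", {
  cp <- oracle_cell()
  syn <- make_synapses(pre = c(1, 2), post = c(2, 3),
                       weight = c(0.4, 0.4), delay = c(2, 3))
  # suprathreshold kicks to neuron 1 at irregular times
  inp <- make_inputs(c(5, 40, 90, 130, 170), 1, 0.4)
  ev <- simulate_circuit(cp, 3, syn, inp, duration_ms = 250)
  fx <- simulate_fixed_step(cp, 3, syn, inp, duration_ms = 250, dt_ms = 0.01)
  expect_equal(nrow(ev$spikes), nrow(fx$spikes))
  expect_equal(ev$spikes$unit_id, fx$spikes$unit_id)
  expect_true(all(abs(ev$spikes$t_ms - fx$spikes$t_ms) <= 0.01 + 1e-9))
})

test_that("oracle equivalence holds on random small circuits with STDP", {
  cp <- oracle_cell()
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(3:5, 1)
    n_syn <- sample(3:6, 1)
    pre <- sample(n, n_syn, replace = TRUE)
    post <- ((pre - 1 + sample(n - 1, n_syn, replace = TRUE)) %% n) + 1
    syn <- make_synapses(pre, post, weight = runif(n_syn, 0.1, 0.35),
                         delay = round(runif(n_syn, 1, 6), 1), plastic = TRUE)
    inp <- make_inputs(sort(round(runif(20, 1, 400), 1)),
                       sample(n, 20, replace = TRUE), 0.38)
    stdp <- list(increment_frac = 0.05, window_ms = 10, wmax_factor = 5)
    ev <- simulate_circuit(cp, n, syn, inp, 450, stdp = stdp)
    fx <- simulate_fixed_step(cp, n, syn, inp, 450, dt_ms = 0.01, stdp = stdp)
    expect_equal(ev$spikes$unit_id, fx$spikes$unit_id)
    # one step of quantization per synaptic hop of the causal chain
    if (nrow(ev$spikes))
      expect_true(all(abs(ev$spikes$t_ms - fx$spikes$t_ms) <= 0.05 + 1e-9))
    expect_equal(ev$weights, fx$weights, tolerance = 1e-9)
  }
})

test_that("synaptic contributions decay exponentially with the receptor tau", {
  # single kick, then a delayed second kick: the residual voltage adds to
  # the new contribution; residual after 5 tau is < 1% (e^-5)
  cp <- oracle_cell(v_threshold = 1000)        # never fires
  syn <- make_synapses()
  w <- 0.2
  tauA <- cp$tau_receptor[["AMPA"]]
  # probe: second identical kick at t2; if residual were zero the voltage
  # would be exactly w*E; threshold set between w*E and w*E(1 + e^-5 + eps)
  v1 <- w * cp$reversal[["AMPA"]]
  for (gap in c(1, 3, 5) * tauA) {
    cp2 <- oracle_cell(v_threshold = v1 * (1 + exp(-gap / tauA) * 0.999))
    r <- simulate_circuit(cp2, 1, syn, make_inputs(c(10, 10 + gap), 1, w), 100)
    expect_equal(nrow(r$spikes), 1L)           # residual pushed it over
    cp3 <- oracle_cell(v_threshold = v1 * (1 + exp(-gap / tauA) * 1.001))
    r2 <- simulate_circuit(cp3, 1, syn, make_inputs(c(10, 10 + gap), 1, w), 100)
    expect_equal(nrow(r2$spikes), 0L)          # residual just short
  }
  expect_lt(exp(-5), 0.01)
})

test_that("AMPA and GABA_A events of matched magnitude cancel", {
  cp <- oracle_cell(tau_receptor = c(AMPA = 10, NMDA = 100, GABA_A = 10),
                    v_threshold = 0.5)
  # one excitatory synapse and one inhibitory synapse with weights chosen
  # so w_e * E_AMPA = -w_i * E_GABA; equal taus; coincident arrival
  w_e <- 0.2
  w_i <- w_e * cp$reversal[["AMPA"]] / -cp$reversal[["GABA_A"]]
  # inhibition lands just before excitation; with equal taus and matched
  # magnitudes the residual displacement is ~ 0.1% of a lone EPSP
  syn <- make_synapses(pre = c(1, 2), post = c(3, 3), weight = c(w_e, w_i),
                       delay = c(1.1, 1.0), channel = c("AMPA", "GABA_A"))
  inp <- make_inputs(c(5, 5), c(1, 2), 0.4)    # drive both sources together
  r <- simulate_circuit(cp, 3, syn, inp, 50)
  expect_false(3 %in% r$spikes$unit_id)        # net displacement ~ 0
  # control: excitation alone fires the target
  syn_e <- make_synapses(1, 3, w_e, 1.1)
  r2 <- simulate_circuit(cp, 3, syn_e, make_inputs(5, 1, 0.4), 50)
  expect_true(3 %in% r2$spikes$unit_id)
})

test_that("zero-weight events leave the neuron silent", {
  cp <- oracle_cell()
  r <- simulate_circuit(cp, 1, make_synapses(),
                        make_inputs(c(5, 10, 15), 1, 0), 50)
  expect_equal(nrow(r$spikes), 0L)
})

test_that("depolarization blockade suppresses firing above v_block", {
  cp <- oracle_cell()
  # a kick that lands between threshold and blockade fires; a kick beyond
  # the blockade voltage does not
  w_fire <- (cp$v_threshold + 5) / cp$reversal[["AMPA"]]
  w_block <- (cp$v_block + 10) / cp$reversal[["AMPA"]]
  r1 <- simulate_circuit(cp, 1, make_synapses(), make_inputs(5, 1, w_fire), 50)
  r2 <- simulate_circuit(cp, 1, make_synapses(), make_inputs(5, 1, w_block), 50)
  expect_equal(nrow(r1$spikes), 1L)
  expect_equal(nrow(r2$spikes), 0L)
  # clamped above blockade by a dense event train -> silent throughout
  r3 <- simulate_circuit(cp, 1, make_synapses(),
                         make_inputs(seq(1, 40, by = 1), 1, w_block), 60)
  expect_equal(nrow(r3$spikes), 0L)
})

test_that("no inter-spike interval violates the absolute refractory period", {
  cp <- oracle_cell(refrac_abs = 2.5)
  # steady subthreshold-summing drive that keeps the cell below blockade
  inp <- make_inputs(seq(1, 99, by = 1.3), 1, 0.15)
  r <- simulate_circuit(cp, 1, make_synapses(), inp, 100)
  expect_gt(nrow(r$spikes), 3)
  expect_true(all(diff(r$spikes$t_ms) > 2.5))
  w <- 0.4
  # second suprathreshold event within refrac_abs never fires
  r2 <- simulate_circuit(cp, 1, make_synapses(),
                         make_inputs(c(10, 11.5), 1, w), 50)
  expect_equal(nrow(r2$spikes), 1L)
})

test_that("relative refractoriness raises the effective threshold and decays", {
  # R > 0: a second kick at the bare-threshold level fails shortly after a
  # spike but succeeds once the threshold offset has decayed (5 tau_R)
  cp <- oracle_cell(refrac_R = 6, tau_R = 10, refrac_H = 0)
  w <- (cp$v_threshold + 2) / cp$reversal[["AMPA"]]
  r_soon <- simulate_circuit(cp, 1, make_synapses(),
                             make_inputs(c(10, 20), 1, w), 100)
  expect_equal(nrow(r_soon$spikes), 1L)        # offset ~ 6 e^-1 = 2.2 > 2
  r_late <- simulate_circuit(cp, 1, make_synapses(),
                             make_inputs(c(10, 10 + 5 * 10), 1, w), 100)
  expect_equal(nrow(r_late$spikes), 2L)        # offset < 1% of R
})

test_that("deliveries arrive at spike time plus synaptic delay", {
  cp <- oracle_cell()
  w <- 0.4
  # axon lengths L and 2L at conduction velocity v: arrival difference L/v
  L <- 400; v <- 1000; base <- 1.5
  syn <- make_synapses(pre = c(1, 1), post = c(2, 3), weight = c(w, w),
                       delay = base + c(L, 2 * L) / v)
  r <- simulate_circuit(cp, 3, syn, make_inputs(100, 1, w), 150)
  t1 <- r$spikes$t_ms[r$spikes$unit_id == 1]
  t2 <- r$spikes$t_ms[r$spikes$unit_id == 2]
  t3 <- r$spikes$t_ms[r$spikes$unit_id == 3]
  expect_equal(t2 - t1, base + L / v, tolerance = 1e-9)
  expect_equal(t3 - t2, L / v, tolerance = 1e-9)
  # no efferent synapses -> no downstream events
  r2 <- simulate_circuit(cp, 2, make_synapses(), make_inputs(10, 1, w), 50)
  expect_equal(sort(unique(r2$spikes$unit_id)), 1L)
})

test_that("STDP potentiates pre-before-post and saturates at 5x baseline", {
  cp <- oracle_cell()
  w0 <- 0.05
  syn <- make_synapses(1, 2, weight = w0, delay = 2, plastic = TRUE)
  stdp <- list(increment_frac = 0.1, window_ms = 10, wmax_factor = 5)
  # pre fires, its input arrives at post 2 ms later, post is forced to
  # fire 3 ms after the arrival -> potentiation each pairing
  n_pair <- 80
  t0 <- seq(10, by = 50, length.out = n_pair)
  inp <- rbind(make_inputs(t0, 1, 0.4), make_inputs(t0 + 5, 2, 0.4))
  inp <- inp[order(inp$time_ms), ]
  r <- simulate_circuit(cp, 2, syn, inp, max(t0) + 20, stdp = stdp)
  expect_equal(r$weights, 5 * w0, tolerance = 1e-12)   # exact saturation
  # reversing the order (post before pre input) depresses to exactly 0
  inp_rev <- rbind(make_inputs(t0, 2, 0.4), make_inputs(t0 + 1, 1, 0.4))
  inp_rev <- inp_rev[order(inp_rev$time_ms), ]
  r2 <- simulate_circuit(cp, 2, syn, inp_rev, max(t0) + 20, stdp = stdp)
  expect_equal(r2$weights, 0, tolerance = 1e-12)
})

test_that("pairings outside the 10 ms window leave the weight unchanged", {
  cp <- oracle_cell()
  syn <- make_synapses(1, 2, weight = 0.05, delay = 2, plastic = TRUE)
  stdp <- list(increment_frac = 0.1, window_ms = 10, wmax_factor = 5)
  t0 <- seq(10, by = 80, length.out = 20)
  inp <- rbind(make_inputs(t0, 1, 0.4), make_inputs(t0 + 2 + 15, 2, 0.4))
  inp <- inp[order(inp$time_ms), ]
  r <- simulate_circuit(cp, 2, syn, inp, max(t0) + 40, stdp = stdp)
  expect_equal(r$weights, 0.05, tolerance = 1e-12)
})

test_that("hebbian weight trajectory is monotone until saturation", {
  cp <- oracle_cell()
  w0 <- 0.05
  syn <- make_synapses(1, 2, weight = w0, delay = 2, plastic = TRUE)
  stdp <- list(increment_frac = 0.04, window_ms = 10, wmax_factor = 5)
  t0 <- seq(10, by = 50, length.out = 30)
  inp <- rbind(make_inputs(t0, 1, 0.4), make_inputs(t0 + 5, 2, 0.4))
  inp <- inp[order(inp$time_ms), ]
  w_end <- vapply(seq(5, 30, by = 5), function(k) {
    simulate_circuit(cp, 2, syn, inp[inp$time_ms <= t0[k] + 20, ],
                     t0[k] + 30, stdp = stdp)$weights
  }, numeric(1))
  expect_true(all(diff(w_end) >= -1e-12))
  expect_true(all(w_end <= 5 * w0 + 1e-12))
})

test_that("identical seeds give bit-identical recordings", {
  cfg <- small_config()
  net <- build_network(cfg, seed = 2)
  sched <- build_session("none", c(5, 0, 0), net, seed = 2)
  a <- run_simulation(net, sched, seed = 2)
  b <- run_simulation(net, sched, seed = 2)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$meta$final_weights, b$meta$final_weights)
  c <- run_simulation(net, sched, seed = 3)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("simulated recordings respect refractoriness and weight bounds", {
  cfg <- small_config()
  net <- build_network(cfg, seed = 4)
  sched <- build_session("none", c(8, 0, 0), net, seed = 4)
  rec <- run_simulation(net, sched, seed = 4)
  refrac <- vapply(net$populations$cell_class,
                   function(cl) cfg$cell_params[[cl]]$refrac_abs, numeric(1))
  by_unit <- split(rec$spikes$time_s * 1000, rec$spikes$unit_id)
  for (u in names(by_unit)) {
    isi <- diff(by_unit[[u]])
    if (length(isi))
      expect_gt(min(isi),
                refrac[match(net$neurons$pop[as.integer(u)],
                             net$populations$name)] - 1e-9)
  }
  w <- rec$meta$final_weights
  expect_true(all(w >= -1e-12))
  expect_true(all(w <= 5 * net$synapses$weight_baseline + 1e-9))
})

test_that("silent network stays silent without drive", {
  cfg <- small_config(background = list(rate_hz = 0, weight = 0,
                                        shared_rate_hz = 0, shared_weight = 0))
  net <- build_network(cfg, seed = 1)
  sched <- build_session("none", c(5, 0, 0), net, seed = 1)
  sched$touch_events <- numeric(0)
  rec <- run_simulation(net, sched, seed = 1)
  expect_equal(nrow(rec$spikes), 0L)
})
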
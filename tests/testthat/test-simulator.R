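test_that("poisson_train has Poisson counts and dispersion", {
  expect_length(poisson_train(0, 1000), 0)
  expect_error(poisson_train(-1, 1000))
  # PV background: 770 Hz over 3000 ms -> mean 2310
  n <- length(poisson_train(770, 3000, seed = 61))
  expect_lt(abs(n - 2310), 5 * sqrt(2310))
  # dispersion: variance ~ mean over repeats
  set.seed(62)
  counts <- replicate(5000, length(poisson_train(25, 1000)))
  expect_lt(abs(stats::var(counts) / mean(counts) - 1), 0.08)
  # trains are sorted and inside (0, duration)
  tr <- poisson_train(100, 500, seed = 63)
  expect_identical(tr, sort(tr))
  expect_true(all(tr > 0 & tr < 500))
})

test_that("gate update is exact exponential decay plus unit increments", {
  expect_identical(update_gate(0, 2, 0.1), 0)
  expect_equal(update_gate(1, 2.0, 2.0), exp(-1))
  expect_equal(update_gate(0, 2.0, 0.1, n_arrivals = 3), 3)
  # vectorized and compositional: two half steps equal one full step
  s <- c(0.2, 1.5, 4)
  expect_equal(update_gate(update_gate(s, 3, 0.05), 3, 0.05),
               update_gate(s, 3, 0.1))
})

test_that("synaptic current follows I = g (V - E) s with reversal clamp", {
  expect_identical(synaptic_current(-60, s = c(0, 0), g = c(1, 2),
                                    E_rev = 0), 0)
  expect_identical(synaptic_current(0, s = 1, g = 1, E_rev = 0), 0)
  # 1 nS * 70 mV = 70 pA of depolarizing drive
  expect_equal(synaptic_current(-70, s = 1, g = 1, E_rev = 0), -70)
  expect_equal(abs(synaptic_current(-70, s = 1, g = 1, E_rev = 0)), 70)
})

test_that("an undriven neuron rests at the leak potential with no spikes", {
  net <- build_network(c(Pyr = 1, PV = 0, SOM = 0, VIP = 0), seed = 1,
                       n_ff_fibers = 1)
  cn <- compile_network(net, 0.1)
  cn$bg_rate[] <- 0
  cn$ff_rate <- 0
  cfg <- simulation_config(duration = 200, discard = 0, n_trials = 1)
  rec <- integrate_trial(cn, cfg, trial_seed = 1, record_v = 1)
  expect_identical(nrow(rec$spikes), 0L)
  expect_true(all(abs(rec$v_trace - (-70)) < 1e-12))
})

test_that("RK4 matches the closed-form response to a constant conductance", {
  # dV/dt = -(V - El)/tau_m - g V / Cm  (reversal 0), V(0) = El
  net <- build_network(c(Pyr = 1, PV = 0, SOM = 0, VIP = 0), seed = 1,
                       n_ff_fibers = 1)
  cn <- compile_network(net, 0.1)
  cn$bg_rate[] <- 0
  cn$ff_rate <- 0
  g <- 3.0
  cfg <- simulation_config(duration = 100, discard = 0, n_trials = 1)
  rec <- integrate_trial(cn, cfg, trial_seed = 1, record_v = 1,
                         const_g_ext = g)
  np <- neuron_params()
  B <- 1 / np$tau_m[1] + g / np$C_m[1]
  Vinf <- (np$E_l[1] / np$tau_m[1]) / B
  t <- (1:1000) * 0.1
  v_exact <- Vinf + (np$E_l[1] - Vinf) * exp(-B * t)
  expect_lt(max(abs(rec$v_trace - v_exact)), 1e-6)
})

test_that("refractory period is respected in full simulated records", {
  net <- small_network(scale = 0.05, seed = 90)
  cfg <- simulation_config(duration = 800, discard = 0, n_trials = 1,
                           scale = 0.05)
  rec <- integrate_trial(net, cfg, trial_seed = 17)
  expect_gt(nrow(rec$spikes), 100)  # meaningful activity
  tau_ref <- neuron_params()$tau_ref
  sp <- split(rec$spikes$time, rec$spikes$neuron_id)
  min_isi_by_class <- tapply(
    vapply(sp, function(tt) if (length(tt) > 1) min(diff(tt)) else Inf, 0),
    rec$class_of[as.integer(names(sp))], min)
  for (k in seq_along(min_isi_by_class)) {
    cls <- as.integer(names(min_isi_by_class)[k])
    expect_gte(min_isi_by_class[[k]], tau_ref[cls] - 1e-9)
  }
  # spike times strictly inside (0, duration]
  expect_true(all(rec$spikes$time > 0 & rec$spikes$time <= 800))
})

test_that("identical seeds give identical spike records", {
  net <- small_network(scale = 0.05, seed = 91)
  cn <- compile_network(net, 0.1)
  cfg <- simulation_config(duration = 500, discard = 0, n_trials = 1,
                           scale = 0.05)
  a <- integrate_trial(cn, cfg, trial_seed = 3)
  b <- integrate_trial(cn, cfg, trial_seed = 3)
  expect_identical(a$spikes, b$spikes)
  d <- integrate_trial(cn, cfg, trial_seed = 4)
  expect_false(identical(a$spikes, d$spikes))
})

test_that("halving dt leaves deterministic firing rates nearly unchanged", {
  # constant-drive neuron spikes periodically; integration-scheme check
  net <- build_network(c(Pyr = 1, PV = 0, SOM = 0, VIP = 0), seed = 1,
                       n_ff_fibers = 1)
  rates <- sapply(c(0.1, 0.05), function(dt) {
    cn <- compile_network(net, dt)
    cn$bg_rate[] <- 0
    cn$ff_rate <- 0
    cfg <- simulation_config(dt = dt, duration = 2000, discard = 0,
                             n_trials = 1)
    rec <- integrate_trial(cn, cfg, trial_seed = 1, const_g_ext = 8.0)
    nrow(rec$spikes) / 2
  })
  expect_gt(rates[1], 5)  # suprathreshold drive
  expect_lt(abs(rates[1] - rates[2]) / rates[2], 0.02)
})

test_that("halving dt changes network rates by less than 2 percent", {
  net <- small_network(scale = 0.1, seed = 92)
  pooled <- vapply(c(0.1, 0.05), function(dt) {
    cn <- compile_network(net, dt)
    cfg <- simulation_config(dt = dt, duration = 1500, n_trials = 1,
                             scale = 0.1)
    counts <- vapply(1:4, function(tr) {
      rec <- integrate_trial(cn, cfg, trial_seed = 200 + tr)
      sum(rec$spikes$time >= 500)
    }, 0)
    mean(counts)
  }, 0)
  expect_lt(abs(pooled[1] - pooled[2]) / pooled[2], 0.02)
})

test_that("feedforward drive monotonically increases Pyr firing", {
  net <- build_network(c(Pyr = 100, PV = 0, SOM = 0, VIP = 0), seed = 95,
                       n_ff_fibers = 50)
  cn <- compile_network(net, 0.1)
  cfg <- simulation_config(duration = 1000, n_trials = 1, scale = 1)
  rates <- sapply(c(10, 25, 60), function(rr) {
    cn2 <- cn
    cn2$ff_rate <- rr
    suppressWarnings(  # only the Pyr class is populated here
      compute_rates(integrate_trial(cn2, cfg, trial_seed = 5),
                    c(500, 1000))[["Pyr"]])
  })
  expect_true(all(diff(rates) > 0))
})

test_that("a purely inhibited neuron never goes below the inhibitory reversal", {
  # Pyr cell receiving only PV input; PV cells driven by background
  sizes <- c(Pyr = 1L, PV = 30L, SOM = 0L, VIP = 0L)
  net <- build_network(sizes, seed = 96, n_ff_fibers = 1)
  cn <- compile_network(net, 0.1)
  cn$bg_rate[cn$class_of == 1] <- 0   # no excitatory drive to the Pyr cell
  cn$ff_rate <- 0
  cfg <- simulation_config(duration = 1000, discard = 0, n_trials = 1)
  rec <- integrate_trial(cn, cfg, trial_seed = 6, record_v = 1)
  expect_gt(nrow(rec$spikes), 0)           # PV cells do fire
  expect_true(all(rec$v_trace >= -70 - 1e-9))
  expect_lt(min(rec$v_trace), -69.99)      # and inhibition does bite
})

test_that("rates are computed as spikes per neuron per second", {
  rec <- make_record(integer(0), numeric(0))
  expect_warning(r0 <- compute_rates(make_record(1, 500,
    sizes = c(Pyr = 1L, PV = 0L, SOM = 0L, VIP = 0L))), "empty class")
  rec1 <- make_record(rep(1L, 10), seq(600, 1499, length.out = 10),
                      sizes = c(Pyr = 1L, PV = 1L, SOM = 1L, VIP = 1L))
  r <- compute_rates(rec1, c(500, 1500))
  expect_equal(r[["Pyr"]], 10)
  expect_equal(r[["PV"]], 0)
  # Poisson rate recovery within CLT bounds
  set.seed(71)
  n_neu <- 50
  tt <- lapply(seq_len(n_neu), function(i) poisson_train(5, 2000))
  rec2 <- make_record(rep(seq_len(n_neu), lengths(tt)), unlist(tt),
                      sizes = c(Pyr = 50L, PV = 0L, SOM = 0L, VIP = 0L),
                      duration = 2000)
  suppressWarnings(r2 <- compute_rates(rec2, c(0, 2000)))
  expect_lt(abs(r2[["Pyr"]] - 5), 4 * sqrt(5 / (50 * 2)))
})
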
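test_that("a leak-only neuron initialized at its reversal is a fixed point", {
  n <- neuron(passive_soma(), v_init = -65)
  tr <- run_simulation(n, sim_config(dt = 0.03125, duration = 10))
  expect_lt(max(abs(tr$V + 65)), 1e-12)
})

test_that("a channel-free, stimulus-free network holds its voltage exactly", {
  n <- neuron(section("s", 50, 2, nseg = 4), v_init = -48)
  tr <- run_simulation(n, sim_config(dt = 0.05, duration = 5))
  expect_lt(max(abs(tr$V + 48)), 1e-10)
})

test_that("runs are deterministic (bit-identical traces) in both modes", {
  b <- build_from_doc(make_fixture("fs_soma_64"))
  st <- stim_pulse(1, 31, 2, 20, 0.3)
  for (mode in c("reference-64bit", "hardware-32bit")) {
    cfg <- sim_config(dt = 0.03125, duration = 30, mode = mode)
    tr1 <- run_simulation(b$network, cfg, st)
    tr2 <- run_simulation(b$network, cfg, st)
    expect_identical(tr1$V, tr2$V)
  }
})

test_that("neurons with zero-weight synapses reproduce their single-neuron traces bit-identically", {
  b <- build_from_doc(make_fixture("fs_soma_64", n_neurons = 2L))
  syn <- synapse_spec(c(1, 63), c(2, 0), "AMPA", gmax = 0.0875, weight = 0)
  st <- stim_pulse(1, 31, 2, 30, 0.3)
  cfg <- sim_config(dt = 0.03125, duration = 40)
  tr_net <- run_simulation(network(b$network$neurons, list(syn)), cfg, st)
  tr_single <- run_simulation(network(b$network$neurons[1]), cfg, st)
  expect_identical(tr_net$V[, 1:64], tr_single$V)
})

test_that("steady-state deflection is linear in injected current in the passive limit", {
  n <- neuron(passive_soma(nseg = 4), v_init = -65)
  cfg <- sim_config(dt = 0.05, duration = 80, record_period = 80)
  defl <- function(amp) {
    tr <- run_simulation(n, cfg, stim_pulse(1, 2, 0, 80, amp))
    tr$V[nrow(tr$V), ] + 65
  }
  d1 <- defl(0.05); d2 <- defl(0.10)
  expect_lt(max(abs(d2 - 2 * d1) / abs(d2)), 1e-9)
})

test_that("one forward step then one reversed step returns the passive voltage", {
  g <- build_grid(passive_soma())
  ax <- precompute_axial(g)
  V0 <- -52.3
  step_with <- function(V, dt) {
    sys <- assemble_system(g, ax, 1e-4, 1e-4 * -65, V, dt = dt)
    advance_full_step(hines_solve(sys), V)
  }
  V1 <- step_with(V0, 0.1)
  V2 <- step_with(V1, -0.1)
  expect_lt(abs(V2 - V0), 1e-12)
})

test_that("active presets rest quietly when initialized at steady state", {
  for (p in c("squid", "fs")) {
    pre <- preset_channels(p)
    n <- neuron(section("soma", 60, 30, nseg = 1, channels = pre$channels),
                v_init = pre$v_init)
    tr <- run_simulation(n, sim_config(dt = 0.03125, duration = 312.5,
                                       record_period = 0.5))
    expect_equal(count_spikes(tr$V[, 1], 0.5), 0L)
    expect_lt(max(tr$V) - min(tr$V), 0.5)   # < 0.5 mV drift over 1e4 steps
  }
})

test_that("initial gate states equal the table fixed points up to discretization", {
  pre <- preset_channels("squid")
  n <- neuron(section("soma", 60, 30, nseg = 1, channels = pre$channels),
              v_init = -65)
  sim <- sim_init(n, sim_config(dt = 0.025))
  for (key in names(sim$gate_blocks)) {
    gb <- sim$gate_blocks[[key]]
    k <- hhcable:::table_index(gb$table, -65)
    fp <- gb$table$r2[k] / (1 - gb$table$r1[k])
    expect_lt(abs(gb$x[1] - fp), 1e-3)
  }
})

test_that("suprathreshold current spikes and subthreshold does not (rheobase order)", {
  b <- build_from_doc(make_fixture("squid_axon_chain"))
  run_amp <- function(amp) {
    tr <- run_simulation(b$network,
                         sim_config(dt = 0.025, duration = 80, record_period = 0.025),
                         stim_pulse(1, 0, 5, 70, amp))
    count_spikes(tr$V[, 1], 0.025)
  }
  expect_equal(run_amp(0.5), 0L)
  expect_gte(run_amp(8), 3L)
})

test_that("a GABA_A synapse from a spiking neuron inhibits its stimulated target", {
  b <- build_from_doc(make_fixture("fs_soma_64", n_neurons = 2L))
  st <- list(stim_pulse(1, 31, 5, 120, 0.3), stim_pulse(2, 31, 5, 120, 0.3))
  cfg <- sim_config(dt = 0.03125, duration = 130, record_period = 0.03125)
  ctrl <- run_simulation(b$network, cfg, st)
  syn <- synapse_spec(c(1, 31), c(2, 31), "GABA_A", gmax = 0.15, weight = 128)
  inh <- run_simulation(network(b$network$neurons, list(syn)), cfg, st)
  late <- ctrl$time > 60
  expect_lt(max(inh$V[late, 64 + 32]), max(ctrl$V[late, 64 + 32]))
  expect_lt(count_spikes(inh$V[, 64 + 32], 0.03125),
            count_spikes(ctrl$V[, 64 + 32], 0.03125))
})

test_that("hardware-32bit mode changes state by at most float32 rounding per step", {
  n <- neuron(passive_soma(), v_init = -55)
  tr64 <- run_simulation(n, sim_config(dt = 0.05, duration = 10))
  tr32 <- run_simulation(n, sim_config(dt = 0.05, duration = 10,
                                       mode = "hardware-32bit"))
  expect_lt(max(abs(tr64$V - tr32$V)), 1e-3)
  expect_identical(as.vector(tr32$V), round_float32(as.vector(tr32$V)))  # binary32 state
})

test_that("recording respects the configured period and row-count contract", {
  n <- neuron(passive_soma(nseg = 64L, L = 70, diam = 9), v_init = -65)
  tr <- run_simulation(n, sim_config(dt = 0.05, duration = 1000, record_period = 1))
  expect_equal(nrow(tr$V), 1001L)
  expect_equal(ncol(tr$V), 64L)
  expect_equal(tr$time[2] - tr$time[1], 1)
  tr0 <- run_simulation(n, sim_config(dt = 0.05, duration = 0))
  expect_equal(nrow(tr0$V), 1L)
})

test_that("invalid stimulus and record targets are rejected by name", {
  n <- neuron(passive_soma(nseg = 4))
  expect_error(run_simulation(n, sim_config(duration = 1),
                              stim_pulse(1, 4, 0, 1, 0.1)), "out of range")
  expect_error(run_simulation(n, sim_config(duration = 1),
                              stim_pulse(2, 0, 0, 1, 0.1)), "does not exist")
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(record_period = 0.01, dt = 0.05), "record period")
})

test_that("autapses are permitted and logged", {
  b <- build_from_doc(make_fixture("fs_soma_64"))
  expect_message(network(b$network$neurons,
                         list(synapse_spec(c(1, 0), c(1, 0), "AMPA", 0.1))),
                 "autapse")
})
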
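test_that("transmitter release triggers on upward crossings only", {
  dt <- 0.1
  # flat at rest: never any transmitter
  st <- list(T = 0, t_remaining = 0)
  last <- -65
  for (i in 1:100) {
    st <- detect_release(-65, last, st$t_remaining, dt)
    expect_equal(st$T, 0)
  }
  # a single upward crossing produces exactly one pulse of Tdur
  vpre <- c(rep(-65, 10), seq(-65, 30, length.out = 10), rep(30, 30), rep(-65, 10))
  trem <- 0; last <- vpre[1]; Ton <- numeric(0)
  for (v in vpre[-1]) {
    st <- detect_release(v, last, trem, dt, threshold = 0, Tmax = 1, Tdur = 1)
    trem <- st$t_remaining; Ton <- c(Ton, st$T); last <- v
  }
  runs <- rle(Ton > 0)
  expect_equal(sum(runs$values), 1L)                 # one pulse
  expect_equal(runs$lengths[runs$values], 10L)       # 1 ms at dt = 0.1
})

test_that("periodic spiking at 50 Hz yields 50 pulses per second", {
  dt <- 0.1
  tt <- seq(0, 1000, by = dt)
  vpre <- ifelse(tt %% 20 < 1, 30, -65)   # 1 ms suprathreshold every 20 ms
  trem <- 0; last <- vpre[1]; n_on <- 0L; prev_on <- FALSE
  for (v in vpre[-1]) {
    st <- detect_release(v, last, trem, dt)
    on <- st$T > 0
    if (on && !prev_on) n_on <- n_on + 1L
    prev_on <- on; trem <- st$t_remaining; last <- v
  }
  expect_equal(n_on, 50L)
})

test_that("receptor kinetics follow the closed-form exponentials", {
  spec <- synapse_spec(c(1, 0), c(1, 0), "AMPA", gmax = 1, weight = 1)
  p <- spec$params
  dt <- 0.05
  # zero weight: no conductance whatever the state
  spec0 <- synapse_spec(c(1, 0), c(1, 0), "AMPA", gmax = 1, weight = 0)
  up <- update_receptor(list(r = 0.7, s = 0), 1, -65, spec0, dt)
  expect_equal(up$g_nS, 0)
  # unbinding decay: half-life ln 2 / beta
  r <- 0.8; st <- list(r = r, s = 0)
  t_half <- log(2) / p$beta
  steps <- round(t_half / dt)
  for (i in seq_len(steps)) st <- update_receptor(st, 0, -65, spec, dt)$state
  expect_equal(st$r, 0.8 * exp(-p$beta * steps * dt), tolerance = 1e-12)
  expect_equal(st$r, 0.4, tolerance = 0.01)
  # sustained transmitter: fixed point alpha*T/(alpha*T + beta)
  st <- list(r = 0, s = 0)
  for (i in 1:4000) st <- update_receptor(st, 1, -65, spec, dt)$state
  expect_equal(st$r, p$alpha / (p$alpha + p$beta), tolerance = 1e-9)
})

test_that("the NMDA magnesium block gates conductance by postsynaptic voltage", {
  expect_equal(mg_block(0), 1 / (1 + 1 / 3.57))
  expect_lt(mg_block(-70), 0.06)
  expect_gt(mg_block(20), 0.8)
  spec <- synapse_spec(c(1, 0), c(1, 0), "NMDA", gmax = 1, weight = 1)
  g_rest <- update_receptor(list(r = 0.5, s = 0), 0, -70, spec, 0.05)$g_nS
  g_dep <- update_receptor(list(r = 0.5, s = 0), 0, 0, spec, 0.05)$g_nS
  expect_gt(g_dep / g_rest, 5)
})

test_that("the GABA_B cascade activates slowly through the Hill function", {
  spec <- synapse_spec(c(1, 0), c(1, 0), "GABA_B", gmax = 1, weight = 1)
  st <- list(r = 0, s = 0)
  g1 <- update_receptor(st, 1, -65, spec, 0.05)
  expect_lt(g1$g_nS, 1e-6)             # nearly no conductance at onset
  st <- g1$state
  for (i in 1:20000) st <- update_receptor(st, 1, -65, spec, 0.05)$state
  p <- spec$params
  r_inf <- p$K1 / (p$K1 + p$K2)
  s_inf <- p$K3 * r_inf / p$K4
  expect_equal(st$s, s_inf, tolerance = 1e-4)
  g_inf <- update_receptor(st, 1, -65, spec, 0.05)$g_nS
  expect_equal(g_inf, s_inf^4 / (s_inf^4 + p$Kd), tolerance = 1e-3)
})

test_that("bound-receptor fraction stays in [0,1] for any pulse train", {
  set.seed(3)
  for (rec in c("AMPA", "NMDA", "GABA_A", "GABA_B")) {
    spec <- synapse_spec(c(1, 0), c(1, 0), rec, gmax = 1, weight = 1)
    st <- list(r = runif(1), s = 0)
    for (i in 1:500) {
      Tc <- sample(c(0, 1), 1)
      st <- update_receptor(st, Tc, runif(1, -80, 20), spec, 0.1)$state
      expect_gte(st$r, 0); expect_lte(st$r, 1)
      expect_gte(st$s, 0)
    }
  }
})

test_that("conductance never exceeds weight * gmax", {
  set.seed(4)
  spec <- synapse_spec(c(1, 0), c(1, 0), "AMPA", gmax = 0.0875, weight = 128)
  st <- list(r = 0, s = 0)
  for (i in 1:500) {
    up <- update_receptor(st, sample(c(0, 1), 1), runif(1, -80, 40), spec, 0.1)
    st <- up$state
    expect_lte(up$g_nS, 128 * 0.0875 + 1e-12)
  }
})

test_that("synaptic accumulation is linear and area-normalized", {
  area <- c(100, 200)   # um^2
  none <- accumulate_synaptic(numeric(0), integer(0), numeric(0), area, 2L)
  expect_equal(none$g_syn, c(0, 0))
  one <- accumulate_synaptic(5, 1L, -80, area, 2L)
  two <- accumulate_synaptic(c(5, 5), c(1L, 1L), c(-80, -80), area, 2L)
  expect_equal(two$g_syn, 2 * one$g_syn)
  expect_equal(two$gE_syn, 2 * one$gE_syn)
  # unit check: 5 nS on 100 um^2 = 5e-9 S / 1e-6 cm^2 = 5e-3 S/cm^2
  expect_equal(one$g_syn[1], 5e-3)
  expect_equal(one$g_syn[2], 0)
})

test_that("fixed-point quantization is idempotent and tightly bounded", {
  set.seed(9)
  x <- runif(1000)
  q <- quantize_fixed(x)
  expect_identical(quantize_fixed(q), q)
  expect_lte(max(abs(q - x)), 2^-19)
  expect_identical(quantize_fixed(0.5), 0.5)
})

test_that("fixed-18bit synapse state deviates at most 2^-17 per step", {
  spec <- synapse_spec(c(1, 0), c(1, 0), "AMPA", gmax = 1, weight = 1)
  dt <- 0.03125
  set.seed(8)
  worst_step <- 0
  for (i in 1:500) {
    r0 <- quantize_fixed(runif(1))
    Tc <- sample(c(0, 1), 1)
    ref <- update_receptor(list(r = r0, s = 0), Tc, -65, spec, dt)$state$r
    worst_step <- max(worst_step, abs(quantize_fixed(ref) - ref))
  }
  expect_lte(worst_step, 2^-17)
  # cumulative drift over a long pulse train stays small (sanity, not a bound
  # the quantization step guarantees)
  r_ref <- 0; r_q <- 0
  for (i in 1:2000) {
    Tc <- if (i %% 300 < 32) 1 else 0
    r_ref <- update_receptor(list(r = r_ref, s = 0), Tc, -65, spec, dt)$state$r
    r_q <- quantize_fixed(update_receptor(list(r = r_q, s = 0), Tc, -65, spec, dt)$state$r)
  }
  expect_lt(abs(r_q - r_ref), 1e-4)
})

test_that("float32 rounding round-trips binary32-representable values", {
  expect_identical(round_float32(c(0.5, 1, -2, 0.25)), c(0.5, 1, -2, 0.25))
  x <- 1/3
  y <- round_float32(x)
  expect_false(identical(x, y))
  expect_lt(abs(x - y), 2^-23)
  expect_identical(round_float32(y), y)   # idempotent
})
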
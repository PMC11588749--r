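test_that("axial couplings reduce to the uniform-cable formula with sealed root", {
  g <- build_grid(section("c", length = 100, diameter = 4, nseg = 5, Ra = 150))
  ax <- precompute_axial(g)
  expect_equal(ax$g[1], 0)                       # sealed end at the root
  a <- 2; dx <- 20
  expect_equal(ax$g[-1], rep(100 * pi * a^2 / (150 * dx), 4))
  # per-area form: dividing by the lateral area 2 pi a dx (in cm^2, uS->S)
  per_area <- ax$g[2] * 1e-6 / (2 * pi * a * dx * 1e-8)
  expect_equal(per_area, (a * 1e-4) / (2 * 150 * (dx * 1e-4)^2), tolerance = 1e-12)
})

test_that("tapered cables give asymmetric per-area coefficients with area-weighted reciprocity", {
  g <- build_grid(section("t", length = 30, diameter = c(6, 2), nseg = 3, Ra = 100))
  ax <- precompute_axial(g)
  areas <- g$area
  # per-area row coefficients (S/cm^2)
  L2 <- ax$g[2] * 1e-6 / (areas[2] * 1e-8)   # row of node 1 coupling to node 0
  U1 <- ax$g[2] * 1e-6 / (areas[1] * 1e-8)   # row of node 0 coupling to node 1
  expect_false(isTRUE(all.equal(L2, U1)))    # asymmetric per-area
  expect_equal(areas[2] * L2, areas[1] * U1, tolerance = 1e-12)  # reciprocity
})

test_that("single-compartment assembly has the expected trivial solutions", {
  g <- build_grid(passive_soma())
  ax <- precompute_axial(g)
  C_nF <- 1 * g$area * 1e-5
  # no channels, no stimulus: isolated capacitor holds its voltage
  sys <- assemble_system(g, ax, 0, 0, V_n = -42, dt = 0.1)
  expect_equal(sys$D, 2 * C_nF / 0.1)
  expect_equal(hines_solve(sys), -42)
  # leak only at its reversal: resting fixed point
  sys2 <- assemble_system(g, ax, 1e-4, 1e-4 * -65, V_n = -65, dt = 0.1)
  expect_equal(hines_solve(sys2), -65)
})

test_that("a 3-node chain matches the dense oracle", {
  set.seed(7)
  g <- build_grid(section("c", 30, 2, nseg = 3))
  ax <- precompute_axial(g)
  sys <- assemble_system(g, ax, rep(1e-4, 3), 1e-4 * c(-65, -60, -70),
                         V_n = c(0, 1, 0), I_inj = c(0, 0, 0.5), dt = 0.05)
  expect_equal(hines_solve(sys), dense_oracle(sys), tolerance = 1e-12)
})

test_that("hines_solve equals the dense LU oracle on chains, Y-trees and random trees", {
  # n = 1
  s1 <- structure(list(p = -1L, D = 4, U = 0, B = 3, n = 1L), class = "hh_system")
  expect_equal(hines_solve(s1), 0.75)
  set.seed(21)
  # 10-node chain
  p <- c(-1L, 0:8)
  gax <- c(0, runif(9, 0.5, 2))
  coup <- gax; for (i in 2:10) coup[p[i] + 1] <- coup[p[i] + 1] + gax[i]
  sys <- structure(list(p = p, D = coup + runif(10, 0.1, 1), U = -gax,
                        B = rnorm(10), n = 10L), class = "hh_system")
  expect_lt(max(abs(hines_solve(sys) - dense_oracle(sys))) /
              max(abs(dense_oracle(sys))), 1e-10)
  # 7-node Y tree: branch at node 2 with children 3 and 5
  sysY <- random_hines_system(7)
  sysY$p <- c(-1L, 0L, 1L, 2L, 3L, 2L, 5L)
  gy <- c(0, runif(6, 0.5, 2))
  cy <- gy; for (i in 2:7) cy[sysY$p[i] + 1] <- cy[sysY$p[i] + 1] + gy[i]
  sysY$D <- cy + runif(7, 0.1, 1); sysY$U <- -gy; sysY$B <- rnorm(7)
  expect_lt(max(abs(hines_solve(sysY) - dense_oracle(sysY))), 1e-10)
  # identity system
  sysI <- structure(list(p = c(-1L, 0L, 1L), D = rep(1, 3), U = rep(0, 3),
                         B = c(5, -3, 2), n = 3L), class = "hh_system")
  expect_equal(dense_oracle(sysI), c(5, -3, 2))
  # seeded random trees with multi-way branches
  for (i in 1:100) {
    sys <- random_hines_system(sample(2:128, 1L))
    vh <- hines_solve(sys); vd <- dense_oracle(sys)
    expect_lt(max(abs(vh - vd)) / max(abs(vd)), 1e-10)
  }
})

test_that("branch-point rows carry exactly 1 + children + parent nonzeros", {
  soma <- section("soma", 20, 10, nseg = 2)
  kids <- lapply(1:3, function(i)
    section(paste0("d", i), 30, 1, nseg = 2,
            parent = list(section = "soma", at = "distal")))
  g <- build_grid(c(list(soma), kids))
  ax <- precompute_axial(g)
  sys <- assemble_system(g, ax, rep(1e-4, g$n_nodes), rep(0, g$n_nodes),
                         rep(-65, g$n_nodes), dt = 0.1)
  M <- matrix(0, sys$n, sys$n)
  diag(M) <- sys$D
  for (i in seq_len(sys$n)) if (sys$p[i] >= 0) {
    M[i, sys$p[i] + 1] <- sys$U[i]; M[sys$p[i] + 1, i] <- sys$U[i]
  }
  nz <- colSums(M != 0)
  branch_row <- 2L  # soma's distal node: parent + 3 children + diagonal
  expect_equal(nz[branch_row], 1L + 3L + 1L)
  expect_equal(nz[1], 1L + 1L)      # root: diagonal + its one child
})

test_that("float32 sweeps agree with double sweeps on well-conditioned systems", {
  set.seed(5)
  sys <- random_hines_system(32)
  expect_lt(max(abs(hines_solve(sys, "float32") - hines_solve(sys))) /
              max(abs(hines_solve(sys))), 1e-5)
})

test_that("singular systems raise a pivot error", {
  sys <- structure(list(p = c(-1L, 0L), D = c(0, 1), U = c(0, 0),
                        B = c(1, 1), n = 2L), class = "hh_system")
  expect_error(hines_solve(sys), "singular")
})

test_that("full-step extrapolation is the 2*Vhalf - Vn identity", {
  expect_equal(advance_full_step(c(1, 2), c(1, 2)), c(1, 2))
  expect_equal(advance_full_step(0, -65), 65)
  expect_error(advance_full_step(c(1, 2), 1), "mismatch")
})

test_that("passive relaxation converges at second order in dt", {
  n <- neuron(passive_soma(), v_init = -55)
  tau <- 1e-3 / 1e-4   # Cm/gL in ms
  errs <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    tr <- run_simulation(n, sim_config(dt = dt, duration = 20, record_period = dt))
    max(abs(tr$V[, 1] - (-65 + 10 * exp(-tr$time / tau))))
  }, 1)
  ratios <- errs[-3] / errs[-1]
  expect_true(all(ratios > 3.5 & ratios < 4.5))
})

test_that("steady-state transfer in a passive tree is reciprocal", {
  soma <- passive_soma(nseg = 3)
  d1 <- section("d1", 200, 2, nseg = 4, channels = list(channel_spec("Leak", 1e-4, -65)),
                parent = list(section = "soma", at = "distal"))
  d2 <- section("d2", 150, 1.5, nseg = 4, channels = list(channel_spec("Leak", 1e-4, -65)),
                parent = list(section = "soma", at = "proximal"))
  g <- build_grid(list(soma, d1, d2))
  ax <- precompute_axial(g)
  n <- g$n_nodes
  transfer <- function(from, to) {
    I <- numeric(n); I[from] <- 0.2
    sys <- assemble_system(g, ax, rep(1e-4, n), rep(1e-4 * -65, n),
                           rep(-65, n), I, dt = Inf)
    hines_solve(sys)[to] + 65
  }
  expect_equal(transfer(2, 10), transfer(10, 2), tolerance = 1e-12)
  expect_equal(transfer(1, 7), transfer(7, 1), tolerance = 1e-12)
})
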
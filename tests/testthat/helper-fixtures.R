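# Shared helpers: small neurons and random structures built in code.

passive_soma <- function(gl = 1e-4, el = -65, nseg = 1L, L = 20, diam = 20) {
  section("soma", length = L, diameter = diam, nseg = nseg,
          channels = list(channel_spec("Leak", gl, el)))
}

# Random Hines-ordered tree as a bare parent vector (0-based), max branch
# degree capped.
random_parent_vector <- function(n, max_children = 4L) {
  p <- integer(n)
  p[1L] <- -1L
  nchild <- integer(n)
  for (i in seq_len(n - 1L)) {
    cand <- which(nchild[seq_len(i)] < max_children)
    par <- if (length(cand) == 1L) cand else sample(cand, 1L)
    p[i + 1L] <- par - 1L
    nchild[par] <- nchild[par] + 1L
  }
  p
}

# Random diagonally dominant symmetric Hines system on a random tree.
random_hines_system <- function(n, max_children = 4L) {
  p <- random_parent_vector(n, max_children)
  g <- c(0, stats::runif(n - 1L, 0.1, 10))    # coupling to parent
  coup <- g
  for (i in seq_len(n)) if (p[i] >= 0L) coup[p[i] + 1L] <- coup[p[i] + 1L] + g[i]
  D <- coup + stats::runif(n, 0.05, 5)        # strictly dominant diagonal
  structure(list(p = p, D = D, U = -g, B = stats::rnorm(n), n = n),
            class = "hh_system")
}

# Passive cable steady-state attenuation error against the sealed-end
# analytic profile cosh((l - x)/lambda)/cosh((l - x0)/lambda), for current
# injected at the first compartment.
cable_profile_error <- function(nseg, gl = 1e-4, Ra = 100, diam = 2, len = 1000) {
  s <- section("cab", len, diam, nseg = nseg, Ra = Ra,
               channels = list(channel_spec("Leak", gl, -65)))
  g <- build_grid(s)
  ax <- precompute_axial(g)
  sys <- assemble_system(g, ax, rep(gl, nseg), rep(gl * -65, nseg),
                         rep(-65, nseg), I_inj = c(0.1, numeric(nseg - 1L)),
                         dt = Inf)
  V <- hines_solve(sys)
  lambda <- sqrt((diam / 2 * 1e-4) / (gl * 2 * Ra))        # cm
  x <- (seq_len(nseg) - 0.5) * (len / nseg) * 1e-4         # cm
  defl <- V + 65
  analytic <- cosh((len * 1e-4 - x) / lambda) / cosh((len * 1e-4 - x[1]) / lambda)
  max(abs(defl / defl[1] - analytic))
}

# Worst-case gate-update error of the nearest-bin table against direct
# evaluation of the premultiplied formulas, over off-center voltages.
table_worst_error <- function(gate, dt, nbins, vmin = -100, vmax = 50,
                              n_probe = 2000L) {
  tb <- build_rate_table(gate, dt, vmin, vmax, nbins)
  v <- seq(vmin, vmax, length.out = n_probe)
  if (gate$formalism == "alpha-beta") {
    r1d <- 1 - dt * (gate$alpha(v) + gate$beta(v))
    r2d <- dt * gate$alpha(v)
  } else {
    r1d <- 1 - dt / gate$tau(v)
    r2d <- dt * gate$inf(v) / gate$tau(v)
  }
  k <- hhcable:::table_index(tb, v)
  x <- 0.5
  max(abs((tb$r1[k] * x + tb$r2[k]) - (r1d * x + r2d)))
}

all_preset_gates <- function() {
  out <- list()
  for (p in c("squid", "fs"))
    for (ch in preset_channels(p)$channels)
      for (g in ch$gates)
        out[[paste(p, ch$name, g$name, sep = ".")]] <- g
  out
}

fs_pair_network <- function(syn = list()) {
  b <- build_from_doc(make_fixture("fs_soma_64", n_neurons = 2L))
  network(b$network$neurons, syn)
}
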
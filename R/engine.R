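#' Assemble a neuron from sections
#'
#' Builds the Hines-ordered compartment grid for a tree of sections (each
#' section carrying its own channel set) and records the resting
#' initialization voltage.
#'
#' @param sections List of [section()] objects (or a single one).
#' @param v_init Resting initialization voltage, mV. Defaults to the leak
#'   reversal of the first section's `"Leak"` channel if present, else -65.
#' @param name Optional label.
#' @return Object of class `"hh_neuron"` with fields `sections`, `grid`,
#'   `v_init`, `name`.
#' @export
neuron <- function(sections, v_init = NULL, name = NULL) {
  grid <- build_grid(sections)
  if (is.null(v_init)) {
    v_init <- -65
    for (sec in grid$sections) for (ch in sec$channels)
      if (ch$name == "Leak") { v_init <- ch$erev; break }
  }
  structure(list(sections = grid$sections, grid = grid, v_init = v_init,
                 name = name),
            class = "hh_neuron")
}

#' Assemble a network of neurons and synapses
#'
#' @param neurons List of [neuron()] objects (or a single one).
#' @param synapses List of [synapse_spec()] objects.
#' @return Object of class `"hh_network"`.
#' @export
network <- function(neurons, synapses = list()) {
  if (inherits(neurons, "hh_neuron")) neurons <- list(neurons)
  if (inherits(synapses, "hh_synapse")) synapses <- list(synapses)
  nn <- vapply(neurons, function(x) x$grid$n_nodes, 1L)
  for (i in seq_along(synapses)) {
    s <- synapses[[i]]
    for (end in c("pre", "post")) {
      k <- s[[end]][1L]; node <- s[[end]][2L]
      if (k < 1L || k > length(neurons))
        stop("synapse ", i, ": ", end, " neuron ", k, " does not exist")
      if (node < 0L || node >= nn[k])
        stop("synapse ", i, ": ", end, " node ", node, " out of range for neuron ",
             k, " (", nn[k], " nodes, 0-based)")
    }
    if (identical(s$pre, s$post))
      message("synapse ", i, ": autapse (pre == post) allowed")
  }
  structure(list(neurons = neurons, synapses = synapses), class = "hh_network")
}

#' Simulation settings
#'
#' @param dt Time step, ms. Default 0.03125 ms, the real-time tick of the
#'   hardware design this engine mirrors.
#' @param duration Simulated time, ms (>= 0).
#' @param mode `"reference-64bit"` (double precision throughout) or
#'   `"hardware-32bit"` (persistent state and the ion-current module's
#'   D/B outputs rounded to IEEE binary32 after each operation group,
#'   nearest-bin table lookup, gates clamped to \[0,1\]).
#' @param synapse_precision `"reference"` or `"fixed-18bit"` (synaptic
#'   kinetic state quantized to 18 fractional bits each step).
#' @param nbins,vmin,vmax Rate-table resolution and voltage range.
#' @param lookup Table lookup rule, `"nearest"` or `"interp"`
#'   (interpolation is a reference-mode refinement; forced to `"nearest"`
#'   in hardware mode).
#' @param record `"all"` or a list of `c(neuron, node)` pairs (0-based
#'   nodes).
#' @param record_period Recording period, ms (>= dt); default `dt` (every
#'   step).
#' @param settle Settling time discarded before t = 0, ms (default 0).
#' @param seed Integer seed stored with the run for provenance.
#' @return Object of class `"hh_config"`.
#' @export
sim_config <- function(dt = 0.03125, duration = 100,
                       mode = c("reference-64bit", "hardware-32bit"),
                       synapse_precision = c("reference", "fixed-18bit"),
                       nbins = 4096L, vmin = -100, vmax = 50,
                       lookup = c("nearest", "interp"),
                       record = "all", record_period = NULL, settle = 0,
                       seed = NULL) {
  mode <- match.arg(mode)
  synapse_precision <- match.arg(synapse_precision)
  lookup <- match.arg(lookup)
  if (mode == "hardware-32bit") lookup <- "nearest"
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.finite(duration) || duration < 0) stop("duration must be >= 0")
  if (is.null(record_period)) record_period <- dt
  if (record_period < dt - 1e-12) stop("record period must be >= dt")
  structure(list(dt = dt, duration = duration, mode = mode,
                 synapse_precision = synapse_precision,
                 nbins = as.integer(nbins), vmin = vmin, vmax = vmax,
                 lookup = lookup, record = record,
                 record_period = record_period, settle = settle, seed = seed),
            class = "hh_config")
}

#' Current pulse stimulus
#'
#' @param neuron 1-based neuron index.
#' @param node 0-based node index.
#' @param onset Pulse onset, ms.
#' @param duration Pulse duration, ms (> 0).
#' @param amplitude Amplitude, nA. Pulses superpose.
#' @return Object of class `"hh_stim"`.
#' @export
stim_pulse <- function(neuron, node, onset, duration, amplitude) {
  if (duration <= 0) stop("stimulus duration must be > 0")
  if (!is.finite(amplitude)) stop("stimulus amplitude must be finite")
  structure(list(neuron = as.integer(neuron), node = as.integer(node),
                 onset = onset, duration = duration, amplitude = amplitude),
            class = "hh_stim")
}

# ---------------------------------------------------------------------------
# Runtime compilation: flatten the network into contiguous arrays (a forest
# with one global Hines parent vector), group gates/channels by identical
# kinetics so the per-step work is a handful of vectorized operations, and
# precompute every per-dt constant.

gate_identity <- function(ch, gt) {
  paste(ch$name, ch$erev, gt$name, gt$formalism, gt$exponent,
        gt$alpha_str %||% "", gt$beta_str %||% "",
        gt$tau_str %||% "", gt$inf_str %||% "",
        paste(names(gt$params), unlist(gt$params), collapse = ","),
        sep = "|")
}

channel_identity <- function(ch) {
  paste(ch$name, ch$erev,
        paste(vapply(ch$gates, function(g) gate_identity(ch, g), ""),
              collapse = "&"), sep = "|")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

compile_network <- function(net, config, stimuli = list()) {
  rt <- new.env(parent = emptyenv())
  neurons <- net$neurons
  nn <- vapply(neurons, function(x) x$grid$n_nodes, 1L)
  offset <- cumsum(c(0L, nn[-length(nn)]))
  n <- sum(nn)
  parent <- integer(n); areas <- Cvec <- numeric(n)
  sec_of <- character(n); npos <- integer(n); neuron_of <- integer(n)
  ax_g <- numeric(n)
  v0 <- numeric(n)
  for (k in seq_along(neurons)) {
    g <- neurons[[k]]$grid
    idx <- offset[k] + seq_len(nn[k])
    pk <- g$parent
    parent[idx] <- ifelse(pk < 0L, -1L, pk + offset[k])
    areas[idx] <- g$area
    Cvec[idx] <- cm_to_nF(g$Cm, g$area)
    sec_of[idx] <- g$section_of
    neuron_of[idx] <- k
    ax_g[idx] <- precompute_axial(g)$g
    v0[idx] <- neurons[[k]]$v_init
  }
  # labels "neuron<k>/<section>[<i>]" with i the node index within its section
  idx_in_sec <- stats::ave(seq_len(n), paste(neuron_of, sec_of),
                           FUN = seq_along) - 1L
  labels <- sprintf("neuron%d/%s[%d]", neuron_of, sec_of, idx_in_sec)

  dt <- config$dt
  # gate + channel blocks grouped by kinetic identity
  gate_blocks <- list(); chan_blocks <- list()
  for (k in seq_along(neurons)) {
    g <- neurons[[k]]$grid
    for (sec in g$sections) {
      nodes <- offset[k] + g$first_node[[sec$name]] + seq_len(sec$nseg)  # 1-based
      for (ch in sec$channels) {
        ckey <- channel_identity(ch)
        if (is.null(chan_blocks[[ckey]])) {
          gids <- character(0)
          for (gt in ch$gates) {
            gkey <- gate_identity(ch, gt)
            gate_blocks[[gkey]] <- list(
              spec = gt, nodes = integer(0),
              table = build_rate_table(gt, dt, config$vmin, config$vmax,
                                       config$nbins))
            gids <- c(gids, gkey)
          }
          chan_blocks[[ckey]] <- list(
            name = ch$name, erev = ch$erev, gate_keys = gids,
            exps = vapply(ch$gates, `[[`, 1L, "exponent"),
            nodes = integer(0), G_uS = numeric(0))
        }
        cb <- chan_blocks[[ckey]]
        cb$nodes <- c(cb$nodes, nodes)
        cb$G_uS <- c(cb$G_uS, density_to_uS(rep(ch$gbar, length(nodes)),
                                            areas[nodes]))
        chan_blocks[[ckey]] <- cb
        for (gkey in cb$gate_keys) {
          gb <- gate_blocks[[gkey]]
          gb$nodes <- c(gb$nodes, nodes)
          gate_blocks[[gkey]] <- gb
        }
      }
    }
  }

  # synapse arrays
  ns <- length(net$synapses)
  syn <- list(n = ns)
  if (ns) {
    sp <- net$synapses
    syn$pre  <- vapply(sp, function(s) offset[s$pre[1L]] + s$pre[2L] + 1L, 1L)
    syn$post <- vapply(sp, function(s) offset[s$post[1L]] + s$post[2L] + 1L, 1L)
    syn$type <- vapply(sp, `[[`, "", "receptor")
    syn$gmax_uS <- vapply(sp, `[[`, 1, "gmax") * 1e-3 *
      vapply(sp, `[[`, 1, "weight")
    syn$erev <- vapply(sp, function(s) s$params$erev, 1)
    syn$thr  <- vapply(sp, function(s) s$params$threshold, 1)
    syn$Tmax <- vapply(sp, function(s) s$params$Tmax, 1)
    syn$Tdur <- vapply(sp, function(s) s$params$Tdur, 1)
    is_b <- syn$type == "GABA_B"
    alpha <- ifelse(is_b, vapply(sp, function(s) s$params$K1 %||% 0, 1),
                    vapply(sp, function(s) s$params$alpha %||% 0, 1))
    beta  <- ifelse(is_b, vapply(sp, function(s) s$params$K2 %||% 0, 1),
                    vapply(sp, function(s) s$params$beta %||% 0, 1))
    kon <- alpha * syn$Tmax + beta
    syn$eon  <- exp(-kon * dt)
    syn$rinf_on <- ifelse(kon > 0, alpha * syn$Tmax / kon, 0)
    syn$eoff <- exp(-beta * dt)
    syn$K4   <- vapply(sp, function(s) s$params$K4 %||% 0, 1)
    K3 <- vapply(sp, function(s) s$params$K3 %||% 0, 1)
    syn$es   <- exp(-syn$K4 * dt)
    syn$sfac <- ifelse(syn$K4 > 0, K3 / syn$K4 * (1 - syn$es), K3 * dt)
    syn$Kd   <- vapply(sp, function(s) s$params$Kd %||% 1, 1)
    syn$nhill <- vapply(sp, function(s) s$params$n %||% 4, 1)
    syn$mg   <- vapply(sp, function(s) s$params$mg %||% 1, 1)
    syn$is_nmda <- syn$type == "NMDA"
    syn$is_b <- is_b
  }

  # stimulus table
  stims <- list()
  for (s in stimuli) {
    if (s$neuron < 1L || s$neuron > length(neurons))
      stop("stimulus: neuron ", s$neuron, " does not exist")
    if (s$node < 0L || s$node >= nn[s$neuron])
      stop("stimulus: node ", s$node, " out of range for neuron ", s$neuron)
    stims[[length(stims) + 1L]] <-
      list(node = offset[s$neuron] + s$node + 1L, onset = s$onset,
           end = s$onset + s$duration, amp = s$amplitude)
  }

  # constant part of the diagonal: axial couplings + 2C/dt
  coup <- ax_g
  has_par <- parent >= 0L
  if (any(has_par))
    coup <- coup + tabulate_weighted(parent[has_par] + 1L, ax_g[has_par], n)
  cap <- 2 * Cvec / dt

  f32 <- config$mode == "hardware-32bit"
  rt$n <- n; rt$parent <- parent; rt$areas <- areas
  rt$neuron_of <- neuron_of; rt$labels <- labels
  rt$U <- -ax_g
  rt$coup <- coup
  rt$D_const <- coup + cap
  rt$cap <- cap
  rt$gate_blocks <- gate_blocks
  rt$chan_blocks <- chan_blocks
  rt$syn <- syn
  rt$stims <- stims
  rt$config <- config
  rt$v0 <- v0
  rt$dt <- dt
  rt$f32 <- f32
  rt$fix18 <- config$synapse_precision == "fixed-18bit"
  rt$clamp <- f32
  rt$step_idx <- 0L
  rt
}

# Initialize V, gate states, synapse states in a compiled runtime.
init_runtime <- function(rt) {
  rt$V <- rt$v0
  for (gkey in names(rt$gate_blocks)) {
    gb <- rt$gate_blocks[[gkey]]
    v <- rt$V[gb$nodes]
    x <- tryCatch(gate_steady_state(gb$spec, v), error = function(e) {
      tb <- gb$table
      k <- table_index(tb, v)
      denom <- 1 - tb$r1[k]
      if (any(denom == 0)) stop("gate '", gb$spec$name,
                                "': steady state undefined at initialization")
      tb$r2[k] / denom
    })
    gb$x <- if (rt$f32) round_float32(x) else x
    rt$gate_blocks[[gkey]] <- gb
  }
  ns <- rt$syn$n
  if (ns) {
    rt$syn_r <- numeric(ns)
    rt$syn_s <- numeric(ns)
    rt$syn_trem <- numeric(ns)
    rt$syn_lastV <- rt$V[rt$syn$pre]
  }
  rt$t <- 0
  rt$step_idx <- 0L
  invisible(rt)
}

# One full step of the pipeline:
# (1) gates from V_n, (2) synapses from previous-step voltages,
# (3) accumulate D/B coefficients, (4) assemble + Hines solve, (5)
# extrapolate to the full step.
step_runtime <- function(rt) {
  V <- rt$V
  n <- rt$n
  # (1) gate update (premultiplied table multiply-add)
  interp <- rt$config$lookup == "interp"
  for (gkey in names(rt$gate_blocks)) {
    gb <- rt$gate_blocks[[gkey]]
    tb <- gb$table
    vi <- V[gb$nodes]
    if (interp) {
      r1 <- interp_table(tb$v, tb$r1, vi)
      r2 <- interp_table(tb$v, tb$r2, vi)
    } else {
      k <- table_index(tb, vi)
      r1 <- tb$r1[k]; r2 <- tb$r2[k]
    }
    x <- r1 * gb$x + r2
    if (rt$clamp) x <- pmin(1, pmax(0, x))
    if (rt$f32) x <- round_float32(x)
    rt$gate_blocks[[gkey]]$x <- x
  }
  # (2) synapses (explicit coupling: previous completed-step voltages)
  g_syn_uS <- NULL
  if (rt$syn$n) {
    sy <- rt$syn
    preV <- V[sy$pre]
    active <- rt$syn_trem > 1e-9
    crossing <- (rt$syn_lastV < sy$thr) & (preV >= sy$thr) & !active
    rt$syn_trem <- ifelse(crossing, sy$Tdur, pmax(0, rt$syn_trem - rt$dt))
    on <- rt$syn_trem > 1e-9
    r <- rt$syn_r
    r <- ifelse(on, sy$rinf_on + (r - sy$rinf_on) * sy$eon, r * sy$eoff)
    s <- rt$syn_s
    if (any(sy$is_b)) s <- s * sy$es + r * sy$sfac
    g <- sy$gmax_uS * r
    if (any(sy$is_nmda)) {
      nm <- sy$is_nmda
      g[nm] <- g[nm] * mg_block(V[sy$post[nm]], sy$mg[nm])
    }
    if (any(sy$is_b)) {
      bb <- sy$is_b
      sn <- s[bb]^sy$nhill[bb]
      g[bb] <- sy$gmax_uS[bb] * sn / (sn + sy$Kd[bb])
    }
    if (rt$fix18) { r <- quantize_fixed(r); s <- quantize_fixed(s) }
    rt$syn_r <- r; rt$syn_s <- s; rt$syn_lastV <- preV
    g_syn_uS <- tabulate_weighted(sy$post, g, n)
    gE_syn <- tabulate_weighted(sy$post, g * sy$erev, n)
  }
  # (3) channel coefficient accumulation (absolute uS / nA)
  G_tot <- numeric(n); GE <- numeric(n)
  for (ckey in names(rt$chan_blocks)) {
    cb <- rt$chan_blocks[[ckey]]
    g <- cb$G_uS
    for (j in seq_along(cb$gate_keys)) {
      x <- rt$gate_blocks[[cb$gate_keys[j]]]$x
      e <- cb$exps[j]
      g <- if (e == 1L) g * x else g * x^e
    }
    G_tot[cb$nodes] <- G_tot[cb$nodes] + g
    GE[cb$nodes] <- GE[cb$nodes] + g * cb$erev
  }
  if (!is.null(g_syn_uS)) {
    G_tot <- G_tot + g_syn_uS
    GE <- GE + gE_syn
  }
  # stimulus current for [t, t+dt)
  I <- numeric(n)
  for (st in rt$stims)
    if (rt$t >= st$onset - 1e-12 && rt$t < st$end - 1e-12)
      I[st$node] <- I[st$node] + st$amp
  # (4) assemble + solve at the half step. In hardware mode the ion-current
  # module's outputs (the membrane parts of D and B) are binary32; the
  # solver initializes the diagonal by adding the stored axial couplings.
  B <- rt$cap * V + GE + I
  if (rt$f32) {
    D <- rt$coup + round_float32(rt$cap + G_tot)
    B <- round_float32(B)
  } else {
    D <- rt$D_const + G_tot
  }
  Vh <- .hines_solve_dbl(rt$parent, D, rt$U, B)
  if (rt$f32) Vh <- round_float32(Vh)
  # (5) extrapolate
  Vn1 <- 2 * Vh - V
  if (rt$f32) Vn1 <- round_float32(Vn1)
  if (anyNA(Vn1) || any(!is.finite(Vn1))) {
    bad <- which(!is.finite(Vn1))[1L]
    stop("non-finite voltage at node ", bad - 1L, " (", rt$labels[bad],
         "), step ", rt$step_idx + 1L)
  }
  rt$V <- Vn1
  rt$t <- rt$t + rt$dt
  rt$step_idx <- rt$step_idx + 1L
  invisible(rt)
}

#' Initialize a simulation
#'
#' Compiles a network + configuration (+ stimuli) into a runtime state
#' object and initializes it: voltages at each neuron's resting
#' initialization value, gates at their steady state for that voltage
#' (computed from the rate functions directly, with the table fixed point
#' `r2/(1 - r1)` as fallback), synapse states zeroed.
#'
#' @param net An `"hh_network"` (or a single `"hh_neuron"`).
#' @param config An [sim_config()].
#' @param stimuli List of [stim_pulse()] objects.
#' @return A runtime environment of class `"hh_sim"`; inspect `$V`, `$t`.
#' @export
sim_init <- function(net, config = sim_config(), stimuli = list()) {
  if (inherits(net, "hh_neuron")) net <- network(list(net))
  if (inherits(stimuli, "hh_stim")) stimuli <- list(stimuli)
  rt <- compile_network(net, config, stimuli)
  init_runtime(rt)
  class(rt) <- c("hh_sim", class(rt))
  rt
}

#' Advance a simulation one time step
#'
#' Runs the per-step pipeline: gate update from the previous voltages,
#' synapse update from previous-step presynaptic voltages, coefficient
#' accumulation, half-step Hines solve, full-step extrapolation.
#'
#' @param sim An `"hh_sim"` from [sim_init()].
#' @return The simulation object, invisibly (state updated in place).
#' @export
sim_step <- function(sim) step_runtime(sim)

#' Run a simulation and record voltage traces
#'
#' Deterministic for a fixed configuration: repeated runs produce
#' bit-identical traces in either numerics mode.
#'
#' @param net An `"hh_network"` or single `"hh_neuron"`.
#' @param config An [sim_config()].
#' @param stimuli List of [stim_pulse()] objects.
#' @return An `"hh_traces"` object: `time` (ms), `V` (matrix, one row per
#'   sample, one column per recorded node), `labels`, `meta` (dt, mode,
#'   config digest, package version).
#' @export
run_simulation <- function(net, config = sim_config(), stimuli = list()) {
  sim <- sim_init(net, config, stimuli)
  if (config$settle > 0)
    for (i in seq_len(round(config$settle / config$dt))) step_runtime(sim)
  sim$t <- 0; sim$step_idx <- 0L

  rec_idx <- record_indices(sim, config$record)
  k_rec <- max(1L, as.integer(round(config$record_period / config$dt)))
  n_steps <- as.integer(round(config$duration / config$dt))
  n_rows <- n_steps %/% k_rec + 1L
  Vmat <- matrix(NA_real_, n_rows, length(rec_idx))
  tvec <- numeric(n_rows)
  Vmat[1L, ] <- sim$V[rec_idx]
  row <- 1L
  for (s in seq_len(n_steps)) {
    step_runtime(sim)
    if (s %% k_rec == 0L) {
      row <- row + 1L
      Vmat[row, ] <- sim$V[rec_idx]
      tvec[row] <- s * config$dt
    }
  }
  structure(list(time = tvec, V = Vmat, labels = sim$labels[rec_idx],
                 meta = list(dt = config$dt, mode = config$mode,
                             synapse_precision = config$synapse_precision,
                             record_period = config$record_period,
                             version = as.character(utils::packageVersion("hhcable")))),
            class = "hh_traces")
}

record_indices <- function(sim, record) {
  if (identical(record, "all")) return(seq_len(sim$n))
  idx <- integer(0)
  offs <- cumsum(c(0L, tabulate(sim$neuron_of)))
  for (r in record) {
    k <- r[1L]; node <- r[2L]
    gi <- which(sim$neuron_of == k)[node + 1L]
    if (is.na(gi)) stop("record: node ", node, " of neuron ", k, " does not exist")
    idx <- c(idx, gi)
  }
  idx
}

#' @export
print.hh_traces <- function(x, ...) {
  cat(sprintf("<hh_traces> %d samples x %d nodes, dt = %g ms, mode = %s\n",
              nrow(x$V), ncol(x$V), x$meta$dt, x$meta$mode))
  invisible(x)
}
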
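# Kinetic conductance-based receptor models (two-state binding scheme, with
# a voltage-dependent magnesium block for NMDA and a second-messenger
# cascade with Hill-type activation for GABA-B). Transmitter is a
# rectangular concentration pulse triggered by a presynaptic voltage
# crossing. The per-step state updates use exact exponential integrators
# whose per-dt rate constants are precomputed once — the software analogue
# of tabulating the exponential rates.

#' Default kinetic receptor parameters
#'
#' The canonical published constants of the two-state kinetic receptor
#' family: binding/unbinding rates, reversal potentials, the NMDA magnesium
#' block, and the GABA-B cascade. Shipped as an overridable list rather
#' than hard-coded; every entry can be replaced per synapse.
#'
#' Units: `alpha` mM^-1 ms^-1, `beta` ms^-1, `erev` mV; GABA-B cascade
#' `K1` mM^-1 ms^-1, `K2`-`K4` ms^-1, `Kd` (half-activation of the Hill
#' term, in s^n units), Hill exponent `n`; transmitter pulse `Tmax` (mM),
#' `Tdur` (ms), release `threshold` (mV).
#'
#' @return Named list with entries `AMPA`, `NMDA`, `GABA_A`, `GABA_B`,
#'   `release`.
#' @export
default_receptor_params <- function() {
  list(
    AMPA   = list(alpha = 1.1,   beta = 0.19,   erev = 0),
    NMDA   = list(alpha = 0.072, beta = 0.0066, erev = 0, mg = 1.0),
    GABA_A = list(alpha = 5.0,   beta = 0.18,   erev = -80),
    GABA_B = list(K1 = 0.09, K2 = 0.0012, K3 = 0.18, K4 = 0.034,
                  Kd = 100, n = 4, erev = -95),
    release = list(threshold = 0, Tmax = 1.0, Tdur = 1.0)
  )
}

#' Voltage-dependent magnesium block of the NMDA receptor
#'
#' `B(V) = 1 / (1 + exp(-0.062 V) * [Mg] / 3.57)` with `[Mg]` in mM.
#'
#' @param V Postsynaptic voltage, mV.
#' @param mg Extracellular magnesium concentration, mM (default 1).
#' @return Unblocked fraction in (0, 1).
#' @export
mg_block <- function(V, mg = 1.0) 1 / (1 + exp(-0.062 * V) * mg / 3.57)

#' Declare one synapse
#'
#' Connects any compartment of any neuron to any other (autapses allowed;
#' an autapse reads the presynaptic voltage of the previous completed step,
#' so within-step update order is immaterial).
#'
#' @param pre,post Length-2 vectors `c(neuron, node)` (1-based neuron index,
#'   0-based node index).
#' @param receptor One of `"AMPA"`, `"NMDA"`, `"GABA_A"`, `"GABA_B"`.
#' @param gmax Maximal conductance, nS (>= 0).
#' @param weight Dimensionless multiplier (>= 0).
#' @param params Optional overrides of [default_receptor_params()] entries
#'   for this synapse (including `erev`, release `threshold`, `Tmax`,
#'   `Tdur`).
#' @return Object of class `"hh_synapse"`.
#' @export
synapse_spec <- function(pre, post, receptor, gmax, weight = 1,
                         params = list()) {
  receptor <- match.arg(receptor, c("AMPA", "NMDA", "GABA_A", "GABA_B"))
  stopifnot(length(pre) == 2L, length(post) == 2L)
  if (!is.finite(gmax) || gmax < 0) stop("synapse: gmax must be >= 0 (nS)")
  if (!is.finite(weight) || weight < 0) stop("synapse: weight must be >= 0")
  defaults <- default_receptor_params()
  p <- utils::modifyList(c(defaults[[receptor]], defaults$release), params)
  structure(list(pre = as.integer(pre), post = as.integer(post),
                 receptor = receptor, gmax = gmax, weight = weight,
                 params = p),
            class = "hh_synapse")
}

#' Update a transmitter release window from the presynaptic voltage
#'
#' Transmitter concentration is a rectangular pulse of amplitude `Tmax`
#' (mM) and duration `Tdur` (ms), triggered when the presynaptic voltage
#' crosses `threshold` upward; a new pulse can be triggered only after the
#' current one has ended.
#'
#' @param pre_V Presynaptic voltage now, mV.
#' @param last_pre_V Presynaptic voltage at the previous step, mV.
#' @param t_remaining Time left in the current pulse, ms (0 if none).
#' @param dt Step, ms.
#' @param threshold,Tmax,Tdur Release parameters (vectors recycled over
#'   synapses).
#' @return List with `T` (current transmitter concentration, mM) and
#'   `t_remaining` (updated clock).
#' @export
detect_release <- function(pre_V, last_pre_V, t_remaining, dt,
                           threshold = 0, Tmax = 1, Tdur = 1) {
  eps <- 1e-9  # absorbs accumulated floating-point residue in the clock
  active <- t_remaining > eps
  crossing <- (last_pre_V < threshold) & (pre_V >= threshold) & !active
  t_remaining <- ifelse(crossing, Tdur, pmax(0, t_remaining - dt))
  list(T = ifelse(t_remaining > eps, Tmax, 0), t_remaining = t_remaining)
}

# Exact exponential update of the two-state binding variable over one step
# with transmitter concentration held at Tc:
#   T on : r -> rinf + (r - rinf) exp(-(alpha*T + beta) dt)
#   T off: r -> r exp(-beta dt)
update_bound_fraction <- function(r, Tc, alpha, beta, dt) {
  k <- alpha * Tc + beta
  rinf <- ifelse(k > 0, alpha * Tc / k, 0)
  rinf + (r - rinf) * exp(-k * dt)
}

#' Advance one synapse's kinetic state and return its conductance
#'
#' Two-state binding for all receptors; the NMDA conductance is multiplied
#' by the magnesium unblock factor at the postsynaptic voltage; GABA-B
#' drives a second-messenger level `s` (`ds/dt = K3 r - K4 s`, exact
#' exponential update with `r` frozen over the step) whose Hill function
#' `s^n / (s^n + Kd)` gates the conductance.
#'
#' @param state List with `r`, `s`, `t_remaining`, `last_pre_V`.
#' @param transmitter Transmitter concentration this step, mM.
#' @param post_V Postsynaptic voltage, mV (used by NMDA only).
#' @param spec An `"hh_synapse"`.
#' @param dt Step, ms.
#' @return List `state` (updated) and `g_nS` (conductance in nS,
#'   already weighted: `weight * gmax * activation`).
#' @export
update_receptor <- function(state, transmitter, post_V, spec, dt) {
  p <- spec$params
  if (spec$receptor == "GABA_B") {
    r <- update_bound_fraction(state$r, transmitter, p$K1, p$K2, dt)
    s <- state$s * exp(-p$K4 * dt) + (p$K3 * r / p$K4) * (1 - exp(-p$K4 * dt))
    sn <- s^p$n
    g <- spec$weight * spec$gmax * sn / (sn + p$Kd)
    state$r <- r; state$s <- s
  } else {
    r <- update_bound_fraction(state$r, transmitter, p$alpha, p$beta, dt)
    g <- spec$weight * spec$gmax * r
    if (spec$receptor == "NMDA") g <- g * mg_block(post_V, p$mg)
    state$r <- r
  }
  if (is.na(g)) stop("NaN synaptic state")
  list(state = state, g_nS = g)
}

#' Sum synaptic conductances into per-node accumulators
#'
#' Converts point conductances (nS) at the postsynaptic compartments to the
#' solver's density units by dividing by the compartment's lateral area and
#' sums them (and the matching `g * Esyn` terms) per node; contributions
#' from multiple synapses on one node add linearly.
#'
#' @param g_nS Per-synapse conductance, nS.
#' @param post_node Per-synapse 1-based global node index.
#' @param erev Per-synapse reversal potential, mV.
#' @param area_um2 Per-node lateral area, um^2.
#' @param n_nodes Total node count.
#' @return List `g_syn` (S/cm^2) and `gE_syn` (S/cm^2 * mV) per node.
#' @export
accumulate_synaptic <- function(g_nS, post_node, erev, area_um2, n_nodes) {
  g_node <- numeric(n_nodes)
  gE_node <- numeric(n_nodes)
  if (length(g_nS)) {
    g_node <- tabulate_weighted(post_node, g_nS, n_nodes)
    gE_node <- tabulate_weighted(post_node, g_nS * erev, n_nodes)
  }
  # nS -> uS -> density S/cm^2 over area: g_uS / (area_cm2 * 1e6)
  conv <- 1e-3 / (area_um2 * 1e-8 * 1e6)
  list(g_syn = g_node * conv, gE_syn = gE_node * conv)
}

#' Quantize values to a signed fixed-point grid
#'
#' Rounds to `frac_bits` fractional bits (`round(x * 2^frac_bits) /
#' 2^frac_bits`), the software emulation of a fixed-point synapse datapath.
#' Idempotent by construction.
#'
#' @param x Numeric vector.
#' @param frac_bits Number of fractional bits (default 18).
#' @return Quantized vector.
#' @export
quantize_fixed <- function(x, frac_bits = 18L) {
  s <- 2^frac_bits
  round(x * s) / s
}

#' Round doubles to IEEE binary32
#'
#' Passes the vector through a 4-byte float representation, reproducing the
#' rounding a 32-bit floating-point datapath applies to stored state.
#'
#' @param x Numeric vector.
#' @return Vector of the same length, each element the nearest binary32
#'   value.
#' @export
round_float32 <- function(x) {
  readBin(writeBin(as.double(x), raw(), size = 4L), what = "double",
          size = 4L, n = length(x))
}
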
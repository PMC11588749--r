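#' Declare a gating variable
#'
#' A gate is a state x in \[0,1\] obeying first-order voltage-dependent
#' kinetics, in either the alpha/beta form
#' `dx/dt = alpha(V) (1 - x) - beta(V) x`
#' or the tau/inf form `dx/dt = (xinf(V) - x)/tau(V)`. The rate functions
#' are given as expression strings over `V` (see [rate_expr()]), so user
#' channels can be declared entirely in configuration files.
#'
#' @param name Gate label (e.g. "m", "h", "n", "p").
#' @param exponent Integer power of this gate in the channel's conductance
#'   product (>= 1).
#' @param alpha,beta Expression strings (ms^-1) for the alpha/beta formalism.
#' @param tau,inf Expression strings (ms, dimensionless) for the tau/inf
#'   formalism. Supply exactly one of the two pairs.
#' @param params Named numeric parameters referenced by the expressions.
#' @return An object of class `"hh_gate"` with evaluator functions attached.
#' @export
gate_spec <- function(name, exponent = 1L, alpha = NULL, beta = NULL,
                      tau = NULL, inf = NULL, params = list()) {
  exponent <- as.integer(exponent)
  if (is.na(exponent) || exponent < 1L) stop("gate '", name, "': exponent must be >= 1")
  ab <- !is.null(alpha) && !is.null(beta)
  ti <- !is.null(tau) && !is.null(inf)
  if (ab == ti)
    stop("gate '", name, "': supply either alpha+beta or tau+inf (exactly one pair)")
  g <- list(name = name, exponent = exponent,
            formalism = if (ab) "alpha-beta" else "tau-inf",
            params = params)
  if (ab) {
    g$alpha <- rate_expr(alpha, params); g$beta <- rate_expr(beta, params)
    g$alpha_str <- alpha; g$beta_str <- beta
  } else {
    g$tau <- rate_expr(tau, params); g$inf <- rate_expr(inf, params)
    g$tau_str <- tau; g$inf_str <- inf
  }
  structure(g, class = "hh_gate")
}

#' Declare a membrane current
#'
#' A conductance-based current `g = gbar * prod(x_i^e_i)` with reversal
#' potential `erev`; a channel with no gates is ohmic (leak).
#'
#' @param name Current label (e.g. "Na", "Kd", "M", "Leak").
#' @param gbar Maximal conductance density, S/cm^2 (>= 0).
#' @param erev Reversal potential, mV.
#' @param gates List of [gate_spec()] objects (empty for leak).
#' @return An object of class `"hh_channel"`.
#' @export
channel_spec <- function(name, gbar, erev, gates = list()) {
  if (!is.finite(gbar) || gbar < 0) stop("channel '", name, "': gbar must be >= 0 (S/cm^2)")
  if (!is.finite(erev)) stop("channel '", name, "': erev must be finite (mV)")
  if (inherits(gates, "hh_gate")) gates <- list(gates)
  structure(list(name = name, gbar = gbar, erev = erev, gates = gates),
            class = "hh_channel")
}

#' Steady-state value of a gate at a voltage
#'
#' Computed from the rate functions directly: `alpha/(alpha+beta)` or
#' `xinf(V)`. Used to initialize gate states at the resting voltage.
#'
#' @param gate An `"hh_gate"`.
#' @param V Voltage(s), mV.
#' @return Steady-state open fraction(s).
#' @export
gate_steady_state <- function(gate, V) {
  if (gate$formalism == "alpha-beta") {
    a <- gate$alpha(V); b <- gate$beta(V)
    s <- a + b
    if (any(s == 0)) stop("gate '", gate$name, "': alpha + beta = 0, steady state undefined")
    a / s
  } else {
    gate$inf(V)
  }
}

#' Build a premultiplied rate table for one gate at a fixed time step
#'
#' Folds the time step into the gate update so a step is one multiply-add:
#' `x <- r1(V) * x + r2(V)`, with
#' `r1 = 1 - dt*(alpha+beta)`, `r2 = dt*alpha` (alpha/beta form) or
#' `r1 = 1 - dt/tau`, `r2 = dt*xinf/tau` (tau/inf form), tabulated at the
#' `nbins` bin-center voltages of `[vmin, vmax]`.
#'
#' A warning is issued if `|r1| >= 1` anywhere on the grid (the explicit
#' gate update is then non-contractive at those voltages, i.e. `dt` exceeds
#' `2/(alpha+beta)` or `2*tau`).
#'
#' @param gate An `"hh_gate"`.
#' @param dt Time step, ms (> 0).
#' @param vmin,vmax Table voltage range, mV.
#' @param nbins Number of bins.
#' @return An object of class `"hh_rate_table"` with fields `vmin`, `vmax`,
#'   `nbins`, `dt`, `r1`, `r2` and the bin-center voltages `v`.
#' @export
build_rate_table <- function(gate, dt, vmin = -100, vmax = 50, nbins = 4096L) {
  stopifnot(dt > 0, vmax > vmin, nbins >= 2L)
  nbins <- as.integer(nbins)
  w <- (vmax - vmin) / nbins
  v <- vmin + (seq_len(nbins) - 0.5) * w
  if (gate$formalism == "alpha-beta") {
    a <- gate$alpha(v); b <- gate$beta(v)
    if (any(!is.finite(a)) || any(!is.finite(b)))
      stop("gate '", gate$name, "': non-finite rate at V = ",
           signif(v[which(!is.finite(a) | !is.finite(b))[1L]], 6), " mV")
    r1 <- 1 - dt * (a + b)
    r2 <- dt * a
  } else {
    tau <- gate$tau(v); xinf <- gate$inf(v)
    if (any(!is.finite(tau)) || any(!is.finite(xinf)) || any(tau <= 0))
      stop("gate '", gate$name, "': invalid tau/xinf on the table range")
    r1 <- 1 - dt / tau
    r2 <- dt * xinf / tau
  }
  if (any(abs(r1) >= 1))
    warning("gate '", gate$name, "': |r1| >= 1 on part of the voltage range; ",
            "dt = ", dt, " ms is too large for a contractive update there")
  structure(list(gate = gate$name, vmin = vmin, vmax = vmax, nbins = nbins,
                 dt = dt, v = v, r1 = r1, r2 = r2),
            class = "hh_rate_table")
}

# Nearest-bin table index for voltages (clamped to the end bins, the
# hardware-style address decode). Returns 1-based indices.
table_index <- function(table, V) {
  w <- (table$vmax - table$vmin) / table$nbins
  k <- floor((V - table$vmin) / w) + 1
  k[k < 1] <- 1L
  k[k > table$nbins] <- table$nbins
  as.integer(k)
}

#' Advance gate states one step from tabulated rates
#'
#' Applies `x <- r1(V) * x + r2(V)` per gate per node, looking `r1`/`r2` up
#' by the membrane voltage of the *previous* time step. The default lookup
#' is nearest-bin; `lookup = "interp"` linearly interpolates between bin
#' centers (reference mode only).
#'
#' @param states Named list of numeric vectors, one per gate (same node
#'   ordering as `V_prev`).
#' @param V_prev Per-node membrane voltage at the previous step, mV.
#' @param tables Named list of `"hh_rate_table"`s, names matching `states`.
#' @param lookup `"nearest"` or `"interp"`.
#' @param clamp If `TRUE`, clamp updated states to \[0,1\] (hardware-faithful
#'   option); default `FALSE`.
#' @return Updated `states` list.
#' @export
update_gates <- function(states, V_prev, tables, lookup = c("nearest", "interp"),
                         clamp = FALSE) {
  lookup <- match.arg(lookup)
  for (nm in names(states)) {
    tb <- tables[[nm]]
    if (is.null(tb)) stop("no rate table for gate '", nm, "'")
    if (lookup == "nearest") {
      k <- table_index(tb, V_prev)
      x <- tb$r1[k] * states[[nm]] + tb$r2[k]
    } else {
      r1 <- interp_table(tb$v, tb$r1, V_prev)
      r2 <- interp_table(tb$v, tb$r2, V_prev)
      x <- r1 * states[[nm]] + r2
    }
    if (clamp) x <- pmin(1, pmax(0, x))
    states[[nm]] <- x
  }
  states
}

# Linear interpolation on bin centers with flat extrapolation.
interp_table <- function(xs, ys, x) {
  stats::approx(xs, ys, xout = pmin(max(xs), pmax(min(xs), x)),
                method = "linear", rule = 2)$y
}

#' Accumulate ionic conductances and driving terms per node
#'
#' For each channel on each node, `g = gbar * prod(x^exponent)`; returns the
#' total membrane conductance density and the matching sum of `g * erev`,
#' the two per-node quantities the half-step system assembly consumes (the
#' D and B channel contributions).
#'
#' @param gate_states Named list of per-node gate state vectors.
#' @param channels List of `"hh_channel"` specs.
#' @param gate_of Optional function mapping (channel name, gate name) to the
#'   key in `gate_states`; default key is `paste(channel, gate, sep = ".")`
#'   falling back to the bare gate name.
#' @param n_nodes Number of nodes (used when `channels` is empty).
#' @return List with `g_tot` (S/cm^2 per node) and `gE_sum` (S/cm^2 * mV per
#'   node).
#' @export
accumulate_currents <- function(gate_states, channels, n_nodes,
                                gate_of = NULL) {
  g_tot <- numeric(n_nodes)
  gE_sum <- numeric(n_nodes)
  for (ch in channels) {
    g <- rep(ch$gbar, n_nodes)
    for (gt in ch$gates) {
      key <- if (!is.null(gate_of)) gate_of(ch$name, gt$name)
             else if (!is.null(gate_states[[paste(ch$name, gt$name, sep = ".")]]))
               paste(ch$name, gt$name, sep = ".") else gt$name
      x <- gate_states[[key]]
      if (is.null(x)) stop("no state for gate '", gt$name, "' of channel '", ch$name, "'")
      g <- g * x^gt$exponent
    }
    if (any(is.na(g))) stop("NaN conductance in channel '", ch$name, "'")
    g_tot <- g_tot + g
    gE_sum <- gE_sum + g * ch$erev
  }
  list(g_tot = g_tot, gE_sum = gE_sum)
}
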
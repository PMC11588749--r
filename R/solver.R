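# Units used by the assembled linear system: conductances in uS,
# capacitance in nF, voltage in mV, time in ms, current in nA. With these,
# uS * mV = nA and nF / ms = uS, so every term of a row is a current in nA
# and the solved unknowns are in mV. Geometry enters in um / um^2 and is
# converted here, in one place.

# Absolute axial conductance (uS) of a cylinder piece: radius a (um),
# length dx (um), axial resistivity Ra (ohm cm).
#   g = pi a^2 / (Ra dx)  [cm units] -> x 100 in (um, ohm cm) -> uS
axial_conductance_uS <- function(a_um, Ra, dx_um) {
  100 * pi * a_um^2 / (Ra * dx_um)
}

# um^2 -> cm^2
area_cm2 <- function(area_um2) area_um2 * 1e-8

# Absolute membrane conductance (uS) from a density (S/cm^2) on area (um^2):
# gbar * area_cm2 * 1e6.
density_to_uS <- function(g_S_cm2, area_um2) g_S_cm2 * area_um2 * 0.01

# Absolute capacitance (nF) from Cm (uF/cm^2) on area (um^2).
cm_to_nF <- function(Cm, area_um2) Cm * area_um2 * 1e-5

#' Precompute axial coupling conductances for a grid
#'
#' For each non-root node, the conductance of the axial path to its parent:
#' `pi * a_interface^2 / (Ra * dx_eff)` in microsiemens, where
#' `a_interface` is the cable radius at the shared compartment boundary and
#' `dx_eff` is the mean of the two compartments' length steps (the series
#' sum of the two half-lengths). Within a section the interface radius is
#' the linearly interpolated radius at the boundary; across a section
#' junction it is the child section's radius at its attachment end. The
#' root entry is 0 (sealed end: no axial current beyond the boundary), and
#' terminal compartments simply have no children, which realizes the sealed
#' distal ends.
#'
#' @param grid An `"hh_grid"`.
#' @return Object of class `"hh_axial"`: numeric vector `g` (uS, aligned to
#'   the child node of each parent link; `g[root] = 0`).
#' @export
precompute_axial <- function(grid) {
  n <- grid$n_nodes
  g <- numeric(n)
  p <- grid$parent
  for (i in seq_len(n)) {
    pi_ <- p[i]
    if (pi_ < 0) next
    j <- pi_ + 1L
    same_sec <- grid$section_of[i] == grid$section_of[j]
    a_int <- if (same_sec) grid$radius_prox[i] else grid$radius_prox[i]
    # across a junction the child's proximal radius is the attachment-end
    # radius by construction (child sections attach by their first node)
    dx_eff <- (grid$dx[i] + grid$dx[j]) / 2
    Ra <- grid$Ra[i]
    g[i] <- axial_conductance_uS(a_int, Ra, dx_eff)
  }
  structure(list(g = g, parent = p), class = "hh_axial")
}

#' Assemble the Crank-Nicholson half-step linear system
#'
#' Builds the symmetric positive-definite tree-tridiagonal system
#' `M V_half = B` for one neuron (or a forest), in absolute units
#' (uS / nF / nA):
#' \itemize{
#'   \item `D[i] = sum(axial couplings at i) + 2 C_i/dt + G_tot_i`
#'   \item `U[i] = -g_axial(i, parent(i))` (the off-diagonal matrix entry)
#'   \item `B[i] = (2 C_i/dt) V_n[i] + GE_sum_i + I_inj[i]`
#' }
#' where `G_tot_i` and `GE_sum_i` are the per-node channel (plus synaptic)
#' conductance density sums scaled by the compartment's lateral area, and
#' `C_i = Cm_i * area_i`. Rows are the area-scaled, sign-flipped form of the
#' per-area half-step equations, which leaves the solution unchanged but
#' makes the matrix symmetric with positive pivots. `dt = Inf` is accepted
#' and drops the capacitive terms, assembling the steady-state system.
#'
#' @param grid An `"hh_grid"`.
#' @param axial Result of [precompute_axial()].
#' @param g_tot Per-node total membrane conductance density, S/cm^2.
#' @param gE_sum Per-node sum of conductance density times reversal,
#'   S/cm^2 * mV.
#' @param V_n Per-node membrane voltage at the current step, mV.
#' @param I_inj Per-node injected current, nA (default none).
#' @param dt Time step, ms (nonzero; negative allowed for reversibility
#'   checks, `Inf` for steady state).
#' @return Object of class `"hh_system"` with `p`, `D`, `U`, `B`, `n`.
#' @export
assemble_system <- function(grid, axial, g_tot, gE_sum, V_n,
                            I_inj = numeric(grid$n_nodes), dt) {
  n <- grid$n_nodes
  if (length(g_tot) != n || length(gE_sum) != n || length(V_n) != n ||
      length(I_inj) != n)
    stop("assemble_system: vector length mismatch (n_nodes = ", n, ")")
  if (!is.finite(dt) && !identical(dt, Inf)) stop("dt must be nonzero (or Inf)")
  if (dt == 0) stop("dt must be nonzero")
  ga <- axial$g
  # sum of couplings incident on each node: own link + links from children
  coup <- ga
  p1 <- axial$parent + 1L
  has_par <- axial$parent >= 0L
  if (any(has_par))
    coup <- coup + unname(tabulate_weighted(p1[has_par], ga[has_par], n))
  cap <- if (is.infinite(dt)) numeric(n) else 2 * cm_to_nF(grid$Cm, grid$area) / dt
  G <- density_to_uS(g_tot, grid$area)
  GE <- density_to_uS(gE_sum, grid$area)  # gE in S/cm^2*mV -> uS*mV = nA
  structure(list(p = axial$parent,
                 D = coup + cap + G,
                 U = -ga,
                 B = cap * V_n + GE + I_inj,
                 n = n),
            class = "hh_system")
}

# weighted tabulate: sum w by integer group index (1..n)
tabulate_weighted <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Solve a Hines system by the parent-vector backward/forward sweeps
#'
#' Backward sweep from the highest-numbered node down to 1: eliminate each
#' node into its parent (`factor = U[i]/D[i]`; `D[p] -= factor*U[i]`;
#' `B[p] -= factor*B[i]`). Forward sweep from the root upward:
#' `V[root] = B/D`, then `V[i] = (B[i] - U[i] V[p[i]])/D[i]`. Linear time
#' and exact (up to rounding) for any Hines-ordered tree or forest.
#'
#' @param system An `"hh_system"`.
#' @param precision `"double"` (default) or `"float32"`, which performs
#'   every sweep operation in IEEE binary32 arithmetic (the hardware-style
#'   datapath).
#' @return Numeric vector of half-step voltages (mV).
#' @export
hines_solve <- function(system, precision = c("double", "float32")) {
  precision <- match.arg(precision)
  if (precision == "double")
    .hines_solve_dbl(as.integer(system$p), system$D, system$U, system$B)
  else
    .hines_solve_f32(as.integer(system$p), system$D, system$U, system$B)
}

#' Dense-matrix oracle for a Hines system
#'
#' Scatters `p`/`D`/`U` into the full symmetric matrix (placing `U[i]` at
#' `(i, p[i])` and `(p[i], i)`) and solves by dense LU factorization. Used
#' as an independent correctness check of [hines_solve()] in tests; never
#' used by the engine.
#'
#' @param system An `"hh_system"`.
#' @return Numeric vector of voltages.
#' @export
dense_oracle <- function(system) {
  n <- system$n
  M <- matrix(0, n, n)
  diag(M) <- system$D
  for (i in seq_len(n)) {
    pi_ <- system$p[i]
    if (pi_ >= 0L) {
      M[i, pi_ + 1L] <- system$U[i]
      M[pi_ + 1L, i] <- system$U[i]
    }
  }
  as.vector(solve(M, system$B))
}

#' Extrapolate the half-step solution to the full step
#'
#' The Crank-Nicholson full-step voltage is `2 V_half - V_n`.
#'
#' @param V_half,V_n Equal-length numeric vectors, mV.
#' @return `2 * V_half - V_n`.
#' @export
advance_full_step <- function(V_half, V_n) {
  if (length(V_half) != length(V_n)) stop("length mismatch")
  2 * V_half - V_n
}
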
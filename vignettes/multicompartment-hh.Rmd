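---
title: "Multicompartment Hodgkin-Huxley simulation with the Hines solver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicompartment Hodgkin-Huxley simulation with the Hines solver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhcable)
```

## The model

`hhcable` simulates networks of morphologically detailed neurons under the
conductance-based (Hodgkin-Huxley) formalism. A neuron is a tree of
unbranched cylindrical cables ("sections"); membrane potential obeys the
one-dimensional cable equation

$$\frac{1}{2\pi a}\frac{\partial}{\partial x}\!\left(\frac{\pi a^2}{R_a}
\frac{\partial V}{\partial x}\right) = C_m \frac{\partial V}{\partial t} +
\sum_k g_k\,(V - E_k) - i_{inj},$$

with $a$ the cable radius, $R_a$ the axial resistivity, $C_m$ the specific
membrane capacitance, and $g_k$ the (gated) membrane conductance densities.
Each section of length $L$ is discretized into `nseg` compartments of width
$\Delta x = L/\mathrm{nseg}$, with voltage evaluated at compartment centers
and the second spatial derivative replaced by the standard three-point
stencil. Sealed ends (no axial current at terminals) fall out of simply
omitting couplings beyond terminal compartments — the discrete equivalent
of mirror "virtual points" at the cable ends.

Gating variables $x \in [0,1]$ follow first-order kinetics in either the
$\alpha/\beta$ or the $\tau/x_\infty$ form. Synapses are kinetic two-state
receptor models (AMPA, NMDA, GABA~A~, GABA~B~) driven by rectangular
transmitter pulses triggered by presynaptic voltage crossings; NMDA carries
a voltage-dependent magnesium block and GABA~B~ a second-messenger cascade
with a Hill-type activation. Any compartment of any neuron can be connected
to any other, each connection independently weighted.

## Integration scheme

Time stepping is Crank-Nicholson in its half-step form: an implicit
(backward-Euler-like) solve to $t + \Delta t/2$,

$$L_i V_{i-1}^{n+1/2} + D_i V_i^{n+1/2} + U_i V_{i+1}^{n+1/2} = B_i,$$

followed by the explicit extrapolation $V^{n+1} = 2V^{n+1/2} - V^n$. This
is second-order accurate and unconditionally stable, which matters for the
stiff, strongly coupled systems produced by fine spatial grids; explicit
integrators would need far smaller steps. The default tick is
$\Delta t = 0.03125$ ms, the update period of the real-time hardware
design whose computation pipeline this package mirrors in software.

Two deliberate choices in the assembly:

* **Sign and symmetry.** The textbook per-area half-step row has a negative
  diagonal and asymmetric axial coefficients $L_i \neq U_i$ (each row is
  normalized by its own compartment's lateral area). We multiply each row
  by that area and flip signs, which leaves the solution unchanged but
  yields a symmetric positive-definite matrix with couplings
  $\pi a_{i\pm1/2}^2/(R_a \Delta x)$ — the two-vector (diagonal + single
  off-diagonal) storage of the parent-vector solver then applies exactly.
  The assembled system uses µS / nF / mV / ms / nA units so that every row
  entry is a current in nA; all µm/cm conversions happen once, inside grid
  construction and assembly.
* **Junctions with unequal $\Delta x$.** The coupling across a section
  junction uses the radius of the child section at its attachment end and
  the mean of the two compartments' length steps (the series sum of two
  half-cables); this reduces to the uniform-grid coefficient on uniform
  grids and preserves the reciprocity of passive transfer, which the test
  suite checks numerically.

The half-step system over the whole *network* is a forest — one tree per
neuron — stored as a single parent vector `p` with `p[i] < i`. One backward
sweep (highest index downward, eliminating each node into its parent) and
one forward substitution solve it in linear time; the sweeps are the one
non-vectorizable loop in the package and are implemented in C++. A dense
LU oracle (`dense_oracle()`) exists purely for verification: the test suite
compares the sweeps against it on hundreds of random trees with branch
degree up to 4 (maximum relative difference observed: ~1e-15, asserted
below 1e-10).

## Premultiplied rate tables

Gate updates use voltage-indexed tables that fold the time step into two
coefficients,

$$x_{n+1} = r_1(V_n)\,x_n + r_2(V_n), \qquad
r_1 = 1 - \Delta t(\alpha + \beta),\quad r_2 = \Delta t\,\alpha$$

(and the analogous $\tau/x_\infty$ forms), so a gate update is one
multiply-add per compartment — the software twin of a hardware lookup
table, where it eliminates division and exponentials from the datapath.
Defaults: range −100..+50 mV, 4096 bins, nearest-bin lookup with
saturation at the end bins (mimicking a finite hardware address decode);
reference mode may instead interpolate linearly between bin centers. At
bin-center voltages the table update is *identical* to direct evaluation of
the rate formulas; between centers the error is bounded by the rates'
modulus of continuity and shrinks with bin count (the suite asserts the
worst-case error at 8192 bins never exceeds that at 1024). The table
builder warns when $|r_1| \ge 1$ anywhere on the grid, i.e. when
$\Delta t$ exceeds $2/(\alpha+\beta)$ or $2\tau$ and the explicit gate
update stops being contractive.

Gates are evaluated from the voltage of the previous completed step and
used directly as the half-step conductances — the literal reading of the
hardware pipeline. A staggered variant (interpolated lookup, reference
mode) is available but off by default.

Because the kinetics of specific channel families are conventions rather
than contributions of this package, rate functions are *data*: expression
strings over `V` in a deliberately tiny language (arithmetic, `exp`, `log`,
and `vtrap(x, y)` for the removable singularity $x/(e^{x/y}-1)$, evaluated
by series near zero). Two presets ship: the textbook squid-axon Na/K/Leak
set, and a fast-spiking cortical-style set (Na, Kd, a small M-type K
current, Leak) built from the standard threshold-shifted rate family whose
densities are documented placeholders, not measurements. Preset `v_init`
values are the self-consistent resting potentials of the full channel sets
(−64.98 mV squid, −71.36 mV fast-spiking), obtained once from a long
settling run; initialization sets every gate to its steady state at that
voltage, so an unstimulated neuron rests quietly (< 0.5 mV drift over
10^4 ticks, asserted). A `settle` option discards an initial transient for
users matching other simulators' initialization conventions.

## Synapse kinetics

Receptor states advance by exact exponential updates with per-`dt` rate
constants precomputed once (the analogue of tabulated exponential rates):
with transmitter on, $r \to r_\infty + (r - r_\infty)e^{-(\alpha T +
\beta)\Delta t}$; with transmitter off, $r \to r\,e^{-\beta \Delta t}$.
This keeps $r \in [0,1]$ for *any* pulse train by construction. Default
binding constants, the magnesium-block curve
$B(V) = 1/(1 + e^{-0.062V}[\mathrm{Mg}]/3.57)$, and the GABA~B~ cascade
constants are the canonical published values of the two-state kinetic
receptor family, shipped as an overridable parameter list
(`default_receptor_params()`), since they are defaults of a cited model
family rather than assertions of this package. Release: a 1 mM, 1 ms
transmitter pulse on an upward crossing of 0 mV, retriggerable after the
pulse ends; all three numbers are configurable. Synaptic conductances are
computed from the presynaptic voltage of the last completed step (explicit
coupling between neurons), so neurons remain independently solvable within
a step and autapses are well-defined.

## Numerics modes

* `reference-64bit` — double precision throughout.
* `hardware-32bit` — emulates a 32-bit floating-point datapath: all
  persistent state (voltages, gate states) and the ion-current module's
  outputs (the membrane contributions to the diagonal and right-hand side)
  are rounded to IEEE binary32 after each operation group, and lookup is
  nearest-bin with gates clamped to [0,1]. The solver adds the stored
  axial couplings to the rounded membrane terms with double accumulation.
  This boundary is deliberate: on a 64-compartment soma the axial coupling
  (~58 µS) exceeds the per-compartment leak conductance (~5e-6 µS) by
  seven orders of magnitude, so rounding the *assembled* diagonal itself
  to binary32 would erase the membrane conductance entirely and bias the
  resting potential by ~10 mV. Rounding at the module boundary instead
  keeps the rest state a fixed point while still exposing every state
  variable to binary32 quantization each tick. The fully-float32 sweep is
  still available as `hines_solve(system, precision = "float32")` for
  studying exactly that conditioning effect.
* `synapse_precision = "fixed-18bit"` — additionally quantizes synaptic
  kinetic state to 18 fractional bits each step (quantization error at
  most $2^{-19}$ per step), emulating a fixed-point synapse unit.

On the 64-compartment fast-spiking demo driven at 0.3 nA for 1000 ms
(32,000 ticks), `hardware-32bit` and `reference-64bit` produce identical
spike counts and a per-compartment RMS voltage difference of ~7e-4 mV.
Both modes are bit-deterministic across repeated runs.

## What the fixtures emulate — and what they do not

`fs_soma_64` is a fast-spiking soma (70 µm × 9 µm, 64 compartments, ~270 Hz
at 0.3 nA). `motoneuron_like_64` reproduces only the *topology* of a
reduced embryonic motor-neuron morphology — soma, active initial segment,
axon chain, three dendrite branches, 64 compartments total — with
placeholder geometry and densities; it is a synthetic stand-in, not the
published reconstruction. `squid_axon_chain` is a 10-compartment axon with
textbook kinetics used for excitability properties: it shows a clean
rheobase (~1.7 nA under its geometry) with monotone spike counts, and —
as the classic squid kinetics do — fires only phasically just above
rheobase, so periodicity checks probe well into the suprathreshold range.
`random_tree` generates seeded random passive trees (≤ 128 compartments)
for structural and solver property tests.

Passing tests on these fixtures demonstrate correctness of the numerics
(convergence orders, oracle equivalence, sign properties of the four
receptor types, mode fidelity) — not biological fidelity of any particular
cell type: the channel densities are placeholders, calcium dynamics,
temperature scaling, stochastic gating and synaptic plasticity are out of
scope, and fixed reversal potentials stand in for ionic concentration
dynamics.

Problem sizes used by the shipped checks were chosen to make each property
measurable while keeping a full run of the suite and the acceptance script
in the minutes range: 500 random trees up to 128 nodes for the solver
oracle, `dt` from 0.05 down to 0.00625 ms for the temporal order, `nseg`
up to 256 for the spatial order, 1000 ms at the 0.03125 ms tick for the
mode-fidelity and scale runs (16 neurons × 64 compartments with 10^4
random synapses).

## Degenerate inputs and tie-breaks

Voltages outside the table range saturate to the end bins. A gate whose
$\alpha + \beta$ vanishes at the initialization voltage falls back to the
table fixed point $r_2/(1-r_1)$; if that is also undefined,
initialization errors out. `dt = Inf` in `assemble_system()` drops the
capacitive terms and yields the steady-state system (used for cable-theory
checks). Negative `dt` is accepted at the assembly level — one forward
step followed by one negated step returns a passive compartment to its
starting voltage to 1e-12, a direct check of the scheme's time symmetry —
while the engine configuration requires `dt > 0`. Elimination declares a
system singular when a pivot's magnitude falls below 1e-300; with positive
capacitive terms this is unreachable. Release clocks compare against a
1e-9 ms epsilon so that accumulated floating-point residue cannot stretch
a transmitter pulse by one tick.
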
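Package: hhcable
Title: Multicompartment Hodgkin-Huxley Neurons on Branched Cables with the
    Hines Solver
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates networks of multicompartment conductance-based
    (Hodgkin-Huxley) neurons. Neuron morphologies are declared as trees of
    unbranched cylindrical sections, discretized into Hines-ordered
    compartment grids, and integrated with a Crank-Nicholson half-step
    scheme whose per-step linear system is solved in linear time by the
    parent-vector (Hines) backward/forward sweeps. Channel gating variables
    advance by premultiplied voltage-indexed rate tables (one multiply-add
    per gate per step), and compartments are coupled across neurons by
    kinetic conductance-based synapse models (AMPA, NMDA, GABA-A, GABA-B).
    A reduced-precision numerics mode (32-bit floating-point state, 18-bit
    fixed-point synapse state) emulates the arithmetic of embedded
    real-time implementations. Includes YAML/JSON configuration I/O, trace
    serialization, demonstration fixtures, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
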
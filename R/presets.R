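# Built-in channel presets.
#
# "squid": the textbook squid-axon Na/K/Leak kinetics (the classic
# voltage-clamp rate functions, voltages in mV relative to a -65 mV rest).
#
# "fs": a fast-spiking cortical interneuron-style set (Na, Kd, a small slow
# non-inactivating K "M" current, Leak) built from the common
# threshold-shifted rate-function family used for cortical neuron models.
# The densities and the threshold parameter below are plausible placeholder
# values for a fast-spiking cell, not measurements; they make a compact
# soma fire tonically at a few hundred pA, which is all the demonstration
# fixtures need.

#' Built-in channel presets
#'
#' @param name `"squid"` (classic squid-axon Na/K/Leak) or `"fs"`
#'   (fast-spiking cortical-style Na/Kd/M/Leak; placeholder densities).
#' @return Named list: `channels` (list of [channel_spec()]), `v_init`
#'   (suggested resting initialization, mV).
#' @examples
#' p <- preset_channels("squid")
#' vapply(p$channels, function(ch) ch$name, "")
#' @export
preset_channels <- function(name = c("squid", "fs")) {
  name <- match.arg(name)
  if (name == "squid") {
    na <- channel_spec("Na", gbar = 0.120, erev = 50, gates = list(
      gate_spec("m", exponent = 3L,
                alpha = "0.1 * vtrap(-(V + 40), 10)",
                beta  = "4 * exp(-(V + 65) / 18)"),
      gate_spec("h", exponent = 1L,
                alpha = "0.07 * exp(-(V + 65) / 20)",
                beta  = "1 / (1 + exp(-(V + 35) / 10))")))
    kd <- channel_spec("Kd", gbar = 0.036, erev = -77, gates = list(
      gate_spec("n", exponent = 4L,
                alpha = "0.01 * vtrap(-(V + 55), 10)",
                beta  = "0.125 * exp(-(V + 65) / 80)")))
    leak <- channel_spec("Leak", gbar = 3e-4, erev = -54.3)
    # resting potential of the full channel set (self-consistent rest from a
    # long settling run; the leak reversal alone is not the rest once the
    # other currents are open at their steady states)
    list(channels = list(na, kd, leak), v_init = -64.9756)
  } else {
    vt <- list(VT = -58)
    na <- channel_spec("Na", gbar = 0.050, erev = 50, gates = list(
      gate_spec("m", exponent = 3L, params = vt,
                alpha = "0.32 * vtrap(-(V - VT - 13), 4)",
                beta  = "0.28 * vtrap(V - VT - 40, 5)"),
      gate_spec("h", exponent = 1L, params = vt,
                alpha = "0.128 * exp(-(V - VT - 17) / 18)",
                beta  = "4 / (1 + exp(-(V - VT - 40) / 5))")))
    kd <- channel_spec("Kd", gbar = 0.010, erev = -90, gates = list(
      gate_spec("n", exponent = 4L, params = vt,
                alpha = "0.032 * vtrap(-(V - VT - 15), 5)",
                beta  = "0.5 * exp(-(V - VT - 10) / 40)")))
    m <- channel_spec("M", gbar = 3e-5, erev = -90, gates = list(
      gate_spec("p", exponent = 1L, params = list(tau_max = 608),
                tau = "tau_max / (3.3 * exp((V + 35) / 20) + exp(-(V + 35) / 20))",
                inf = "1 / (1 + exp(-(V + 35) / 10))")))
    leak <- channel_spec("Leak", gbar = 1.5e-5, erev = -70.4)
    list(channels = list(na, kd, m, leak), v_init = -71.3587)
  }
}
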
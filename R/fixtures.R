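# Demonstration fixtures. All are generated programmatically; none ship as
# data files.

channels_doc_preset <- function(preset) list(preset = preset)

#' Generate a demonstration configuration document
#'
#' Fixtures:
#' \describe{
#'   \item{`fs_soma_64`}{Fast-spiking neuron somas: one section of 70 um
#'     length and 9 um diameter divided into 64 compartments, carrying the
#'     `"fs"` channel preset. `n_neurons` copies (default 1).}
#'   \item{`motoneuron_like_64`}{A branched motor-neuron-like tree of
#'     exactly 64 compartments: soma, an active axon initial segment, an
#'     axon chain, and three dendrite branches. The topology emulates a
#'     reduced embryonic motor-neuron morphology; lengths, diameters and
#'     densities are synthetic placeholder values, not measurements.}
#'   \item{`squid_axon_chain`}{An unbranched 10-compartment axon with the
#'     classic squid Na/K/Leak kinetics; used for excitability tests.}
#'   \item{`random_tree`}{A seeded random passive tree with up to 128
#'     compartments and valid random geometry.}
#' }
#'
#' @param name Fixture name.
#' @param seed Integer seed (used by `random_tree` only).
#' @param n_neurons Number of neuron copies (supported by `fs_soma_64`).
#' @return A configuration document (named list) ready for [save_config()],
#'   [validate_config_doc()], or direct building via [load_config()]'s
#'   internals; pass to [build_from_doc()] to obtain runnable objects.
#' @export
make_fixture <- function(name = c("fs_soma_64", "motoneuron_like_64",
                                  "squid_axon_chain", "random_tree"),
                         seed = 1L, n_neurons = 1L) {
  name <- match.arg(name)
  doc <- switch(name,
    fs_soma_64 = {
      one <- list(name = "fs", v_init = -71.3587, sections = list(
        list(name = "soma", length = 70, diameter = 9, nseg = 64L,
             Ra = 100, Cm = 1, channels = channels_doc_preset("fs"))))
      neurons <- lapply(seq_len(n_neurons), function(k) {
        x <- one; x$name <- paste0("fs", k); x })
      list(neurons = neurons,
           simulation = list(dt = 0.03125, duration = 200))
    },
    motoneuron_like_64 = {
      # 4 + 4 + 24 + 16 + 8 + 8 = 64 compartments
      secs <- list(
        list(name = "soma", length = 30, diameter = 20, nseg = 4L,
             Ra = 125, Cm = 1, channels = channels_doc_preset("squid")),
        list(name = "ais", length = 40, diameter = 2, nseg = 4L,
             Ra = 125, Cm = 1, channels = channels_doc_preset("squid"),
             parent = list(section = "soma", at = "distal")),
        list(name = "axon", length = 600, diameter = 1.5, nseg = 24L,
             Ra = 125, Cm = 1, channels = channels_doc_preset("squid"),
             parent = list(section = "ais", at = "distal")),
        list(name = "dend1", length = 400, diameter = c(4, 1), nseg = 16L,
             Ra = 125, Cm = 1,
             channels = list(list(name = "Leak", gbar = 3e-4, erev = -54.3)),
             parent = list(section = "soma", at = "proximal")),
        list(name = "dend2", length = 250, diameter = c(3, 1), nseg = 8L,
             Ra = 125, Cm = 1,
             channels = list(list(name = "Leak", gbar = 3e-4, erev = -54.3)),
             parent = list(section = "dend1", at = "distal")),
        list(name = "dend3", length = 250, diameter = c(3, 1), nseg = 8L,
             Ra = 125, Cm = 1,
             channels = list(list(name = "Leak", gbar = 3e-4, erev = -54.3)),
             parent = list(section = "dend1", at = "distal")))
      list(neurons = list(list(name = "mn", v_init = -65, sections = secs)),
           stimuli = list(list(neuron = 1L, node = 0L, onset = 5,
                               duration = 15, amplitude = 2)),
           simulation = list(dt = 0.03125, duration = 50))
    },
    squid_axon_chain = {
      list(neurons = list(list(name = "squid", v_init = -64.9756, sections = list(
             list(name = "axon", length = 500, diameter = 50, nseg = 10L,
                  Ra = 35.4, Cm = 1,
                  channels = channels_doc_preset("squid"))))),
           simulation = list(dt = 0.025, duration = 100))
    },
    random_tree = {
      set.seed(seed)
      n_secs <- sample(3:10, 1L)
      secs <- list(list(name = "sec1",
                        length = stats::runif(1, 20, 200),
                        diameter = stats::runif(1, 1, 10),
                        nseg = sample(1:12, 1L), Ra = 100, Cm = 1,
                        channels = list(list(name = "Leak", gbar = 1e-4,
                                             erev = -65))))
      for (i in 2:n_secs) {
        par <- sample(i - 1L, 1L)
        secs[[i]] <- list(name = paste0("sec", i),
                          length = stats::runif(1, 20, 200),
                          diameter = stats::runif(1, 0.5, 6),
                          nseg = sample(1:12, 1L), Ra = 100, Cm = 1,
                          channels = list(list(name = "Leak", gbar = 1e-4,
                                               erev = -65)),
                          parent = list(section = paste0("sec", par),
                                        at = sample(c("proximal", "distal"), 1L)))
      }
      # cap the total at 128 compartments
      tot <- sum(vapply(secs, function(s) s$nseg, 1L))
      while (tot > 128L) {
        i <- which.max(vapply(secs, function(s) s$nseg, 1L))
        secs[[i]]$nseg <- max(1L, secs[[i]]$nseg %/% 2L)
        tot <- sum(vapply(secs, function(s) s$nseg, 1L))
      }
      list(neurons = list(list(name = "rand", v_init = -65, sections = secs)),
           simulation = list(dt = 0.05, duration = 20, seed = seed))
    })
  doc
}

#' Build runnable objects from a configuration document
#'
#' The in-memory counterpart of [load_config()]: validates `doc` and
#' returns the network, simulation settings, stimuli, and digest.
#'
#' @param doc A configuration document (e.g. from [make_fixture()]).
#' @return List with `network`, `config`, `stimuli`, `digest`.
#' @export
build_from_doc <- function(doc) {
  errs <- validate_config_doc(doc)
  if (length(errs))
    stop("configuration schema errors:\n  ", paste(errs, collapse = "\n  "))
  list(network = doc_to_network(doc), config = doc_to_sim(doc),
       stimuli = doc_to_stimuli(doc), digest = config_digest(doc))
}
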
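# Configuration documents.
#
# A network is declared in a structured-text document (YAML or JSON; the
# schema is identical) with blocks: neurons (sections + channels), synapses
# (list or dense weight-matrix form), stimuli, simulation. Documents are
# strictly validated: unknown keys are rejected with their location, and a
# content digest (canonicalized, key order irrelevant) identifies the
# configuration in trace metadata.

CONFIG_KEYS <- list(
  top = c("neurons", "synapses", "stimuli", "simulation"),
  neuron = c("name", "v_init", "sections"),
  section = c("name", "length", "diameter", "nseg", "Ra", "Cm", "parent",
              "channels"),
  parent = c("section", "at"),
  channel = c("name", "gbar", "erev", "gates"),
  gate = c("name", "exponent", "alpha", "beta", "tau", "inf", "params"),
  synapse = c("pre", "post", "receptor", "gmax", "weight", "params"),
  dense = c("dense"),
  dense_block = c("receptor", "gmax", "weights", "params"),
  stimulus = c("neuron", "node", "onset", "duration", "amplitude"),
  simulation = c("dt", "duration", "mode", "synapse_precision", "nbins",
                 "vmin", "vmax", "lookup", "record", "record_period",
                 "settle", "seed"))

check_keys <- function(x, allowed, where, errors) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    errors <- c(errors, sprintf("%s: unknown key(s) %s", where,
                                paste(sQuote(unknown), collapse = ", ")))
  errors
}

#' Validate a configuration document
#'
#' Checks the document structure against the schema: required blocks,
#' unknown keys (rejected, with their path), reference integrity (synapse
#' and stimulus endpoints must name existing neurons/nodes).
#'
#' @param doc A named list (as returned by [yaml::read_yaml()] /
#'   [jsonlite::read_json()] or [make_fixture()]).
#' @return Character vector of schema errors with paths; empty if valid.
#' @export
validate_config_doc <- function(doc) {
  errors <- character(0)
  if (!is.list(doc)) return("document: not a mapping")
  errors <- check_keys(doc, CONFIG_KEYS$top, "document", errors)
  if (is.null(doc$neurons) || !length(doc$neurons)) {
    errors <- c(errors, "document: no 'neurons' block")
    return(errors)
  }
  n_nodes <- integer(0)
  for (i in seq_along(doc$neurons)) {
    ne <- doc$neurons[[i]]
    w <- sprintf("neurons[%d]", i)
    errors <- check_keys(ne, CONFIG_KEYS$neuron, w, errors)
    if (is.null(ne$sections) || !length(ne$sections)) {
      errors <- c(errors, paste0(w, ": no sections")); next
    }
    tot <- 0L
    for (j in seq_along(ne$sections)) {
      se <- ne$sections[[j]]
      ws <- sprintf("%s.sections[%d]", w, j)
      errors <- check_keys(se, CONFIG_KEYS$section, ws, errors)
      for (req in c("name", "length", "diameter", "nseg"))
        if (is.null(se[[req]]))
          errors <- c(errors, sprintf("%s: missing '%s'", ws, req))
      if (!is.null(se$nseg)) tot <- tot + as.integer(se$nseg)
      if (!is.null(se$parent) && is.list(se$parent))
        errors <- check_keys(se$parent, CONFIG_KEYS$parent,
                             paste0(ws, ".parent"), errors)
      ch <- se$channels
      if (!is.null(ch) && is.list(ch) && is.null(ch$preset)) {
        for (c_i in seq_along(ch)) {
          errors <- check_keys(ch[[c_i]], CONFIG_KEYS$channel,
                               sprintf("%s.channels[%d]", ws, c_i), errors)
          for (g_i in seq_along(ch[[c_i]]$gates))
            errors <- check_keys(ch[[c_i]]$gates[[g_i]], CONFIG_KEYS$gate,
                                 sprintf("%s.channels[%d].gates[%d]", ws, c_i, g_i),
                                 errors)
        }
      } else if (is.list(ch) && !is.null(ch$preset)) {
        errors <- check_keys(ch, c("preset", "gbar"), paste0(ws, ".channels"),
                             errors)
        if (!ch$preset %in% c("squid", "fs", "passive"))
          errors <- c(errors, sprintf("%s.channels: unknown preset '%s'", ws,
                                      ch$preset))
      }
    }
    n_nodes <- c(n_nodes, tot)
  }
  syn <- doc$synapses
  if (!is.null(syn)) {
    if (is.list(syn) && !is.null(syn$dense)) {
      errors <- check_keys(syn, CONFIG_KEYS$dense, "synapses", errors)
      errors <- check_keys(syn$dense, CONFIG_KEYS$dense_block,
                           "synapses.dense", errors)
      if (sum(n_nodes) > 64L)
        errors <- c(errors,
                    "synapses.dense: dense weight matrix only supported for <= 64 total nodes")
      w <- syn$dense$weights
      if (!is.null(w)) {
        w <- as_matrix(w)
        if (nrow(w) != sum(n_nodes) || ncol(w) != sum(n_nodes))
          errors <- c(errors, sprintf(
            "synapses.dense.weights: must be %d x %d (total nodes)",
            sum(n_nodes), sum(n_nodes)))
      }
    } else {
      for (i in seq_along(syn)) {
        s <- syn[[i]]
        ws <- sprintf("synapses[%d]", i)
        errors <- check_keys(s, CONFIG_KEYS$synapse, ws, errors)
        for (req in c("pre", "post", "receptor", "gmax"))
          if (is.null(s[[req]]))
            errors <- c(errors, sprintf("%s: missing '%s'", ws, req))
        for (end in c("pre", "post")) {
          ep <- unlist(s[[end]])
          if (length(ep) == 2L) {
            k <- ep[1L]; node <- ep[2L]
            if (k < 1 || k > length(n_nodes))
              errors <- c(errors, sprintf("%s.%s: neuron %d does not exist", ws, end, k))
            else if (node < 0 || node >= n_nodes[k])
              errors <- c(errors, sprintf(
                "%s.%s: node %d out of range for neuron %d (%d nodes, 0-based)",
                ws, end, node, k, n_nodes[k]))
          } else errors <- c(errors, sprintf("%s.%s: must be [neuron, node]", ws, end))
        }
        if (!is.null(s$receptor) &&
            !s$receptor %in% c("AMPA", "NMDA", "GABA_A", "GABA_B"))
          errors <- c(errors, sprintf("%s: unknown receptor '%s'", ws, s$receptor))
      }
    }
  }
  for (i in seq_along(doc$stimuli)) {
    s <- doc$stimuli[[i]]
    ws <- sprintf("stimuli[%d]", i)
    errors <- check_keys(s, CONFIG_KEYS$stimulus, ws, errors)
    for (req in c("neuron", "node", "onset", "duration", "amplitude"))
      if (is.null(s[[req]])) errors <- c(errors, sprintf("%s: missing '%s'", ws, req))
    if (!is.null(s$neuron) && (s$neuron < 1 || s$neuron > length(n_nodes)))
      errors <- c(errors, sprintf("%s: neuron %d does not exist", ws, s$neuron))
    else if (!is.null(s$node) && !is.null(s$neuron) &&
             (s$node < 0 || s$node >= n_nodes[s$neuron]))
      errors <- c(errors, sprintf("%s: node %d out of range for neuron %d",
                                  ws, s$node, s$neuron))
  }
  if (!is.null(doc$simulation))
    errors <- check_keys(doc$simulation, CONFIG_KEYS$simulation, "simulation",
                         errors)
  errors
}

as_matrix <- function(w) {
  if (is.matrix(w)) w else do.call(rbind, lapply(w, unlist))
}

channels_from_doc <- function(ch) {
  if (is.null(ch) || !length(ch)) return(list())
  if (is.list(ch) && !is.null(ch$preset)) {
    if (ch$preset == "passive") return(list())
    pl <- preset_channels(ch$preset)$channels
    if (!is.null(ch$gbar))
      for (i in seq_along(pl))
        if (!is.null(ch$gbar[[pl[[i]]$name]]))
          pl[[i]]$gbar <- ch$gbar[[pl[[i]]$name]]
    return(pl)
  }
  lapply(ch, function(c_) {
    gates <- lapply(c_$gates, function(g)
      gate_spec(g$name, exponent = g$exponent %||% 1L,
                alpha = g$alpha, beta = g$beta, tau = g$tau, inf = g$inf,
                params = g$params %||% list()))
    channel_spec(c_$name, gbar = c_$gbar, erev = c_$erev, gates = gates)
  })
}

doc_to_network <- function(doc) {
  neurons <- lapply(doc$neurons, function(ne) {
    secs <- lapply(ne$sections, function(se) {
      par <- se$parent
      if (is.character(par)) par <- list(section = par, at = "distal")
      section(se$name, length = se$length, diameter = unlist(se$diameter),
              nseg = se$nseg %||% 1L, Ra = se$Ra %||% 100, Cm = se$Cm %||% 1,
              channels = channels_from_doc(se$channels), parent = par)
    })
    neuron(secs, v_init = ne$v_init, name = ne$name)
  })
  synapses <- list()
  syn <- doc$synapses
  if (!is.null(syn)) {
    if (is.list(syn) && !is.null(syn$dense)) {
      d <- syn$dense
      w <- as_matrix(d$weights)
      nn <- vapply(neurons, function(x) x$grid$n_nodes, 1L)
      noff <- cumsum(c(0L, nn[-length(nn)]))
      glob2pair <- function(g) {
        k <- findInterval(g - 1L, noff)
        c(k, g - 1L - noff[k])
      }
      nz <- which(w != 0, arr.ind = TRUE)
      synapses <- lapply(seq_len(nrow(nz)), function(r)
        synapse_spec(pre = glob2pair(nz[r, 1L]), post = glob2pair(nz[r, 2L]),
                     receptor = d$receptor, gmax = d$gmax,
                     weight = w[nz[r, 1L], nz[r, 2L]],
                     params = d$params %||% list()))
    } else {
      synapses <- lapply(syn, function(s)
        synapse_spec(pre = unlist(s$pre), post = unlist(s$post),
                     receptor = s$receptor, gmax = s$gmax,
                     weight = s$weight %||% 1,
                     params = s$params %||% list()))
    }
  }
  network(neurons, synapses)
}

doc_to_sim <- function(doc) {
  s <- doc$simulation %||% list()
  rec <- s$record %||% "all"
  if (is.list(rec)) rec <- lapply(rec, unlist)
  sim_config(dt = s$dt %||% 0.03125, duration = s$duration %||% 100,
             mode = s$mode %||% "reference-64bit",
             synapse_precision = s$synapse_precision %||% "reference",
             nbins = s$nbins %||% 4096L, vmin = s$vmin %||% -100,
             vmax = s$vmax %||% 50, lookup = s$lookup %||% "nearest",
             record = rec, record_period = s$record_period,
             settle = s$settle %||% 0, seed = s$seed)
}

doc_to_stimuli <- function(doc) {
  lapply(doc$stimuli %||% list(), function(s)
    stim_pulse(s$neuron, s$node, s$onset, s$duration, s$amplitude))
}

#' Load and validate a configuration file
#'
#' Accepts YAML or JSON (detected by extension, falling back to trying
#' both). The document is schema-validated; on success the fully built
#' object graph is returned together with the filled-in simulation settings
#' and the content digest.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` configuration file.
#' @return List with `network` (`"hh_network"`), `config` (`"hh_config"`),
#'   `stimuli`, `doc` (the raw document) and `digest`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
         else yaml::read_yaml(path)
  errs <- validate_config_doc(doc)
  if (length(errs))
    stop("configuration schema errors in ", path, ":\n  ",
         paste(errs, collapse = "\n  "))
  list(network = doc_to_network(doc), config = doc_to_sim(doc),
       stimuli = doc_to_stimuli(doc), doc = doc, digest = config_digest(doc))
}

#' Write a configuration document to a file
#'
#' @param doc A configuration document (named list).
#' @param path Destination ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
save_config <- function(doc, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json")
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  else yaml::write_yaml(doc, path)
  invisible(path)
}

# Recursively sort names so the digest is independent of key order.
canonicalize <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, canonicalize)
    if (!is.null(names(x)) && any(nzchar(names(x))))
      x <- x[order(names(x))]
  }
  x
}

#' Content digest of a configuration document
#'
#' MD5 of the canonicalized (recursively key-sorted) JSON serialization:
#' stable under key reordering and comment changes, different whenever a
#' semantically meaningful field differs.
#'
#' @param doc A configuration document (named list).
#' @return Hex digest string.
#' @export
config_digest <- function(doc) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canonicalize(doc), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}
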
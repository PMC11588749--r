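#' Declare an unbranched cylindrical section
#'
#' A section is the unit of morphology description: an unbranched cable of
#' homogeneous electrical properties (soma, axon segment, dendrite branch),
#' subdivided into `nseg` compartments of equal length when discretized by
#' [build_grid()].
#'
#' @param name Section label, unique within a neuron.
#' @param length Section length in micrometers.
#' @param diameter Diameter in micrometers. Either a single value (uniform
#'   cylinder) or a length-2 vector `c(proximal, distal)`; a tapered section
#'   interpolates the diameter linearly along its length.
#' @param nseg Number of compartments the section is divided into (>= 1).
#' @param Ra Axial resistivity in ohm cm.
#' @param Cm Specific membrane capacitance in microfarad per square cm.
#' @param channels List of [channel_spec()] objects giving the membrane
#'   currents present on this section (may be empty for a purely passive
#'   section, which then has zero membrane conductance).
#' @param parent Either `NULL` (root section) or a list/character giving the
#'   parent section name and the attachment end, e.g.
#'   `list(section = "soma", at = "distal")`. `at` defaults to `"distal"`.
#' @return An object of class `"hh_section"`.
#' @examples
#' soma <- section("soma", length = 70, diameter = 9, nseg = 64)
#' dend <- section("dend", length = 200, diameter = 2, nseg = 10,
#'                 parent = list(section = "soma", at = "distal"))
#' @export
section <- function(name, length, diameter, nseg = 1L, Ra = 100, Cm = 1,
                    channels = list(), parent = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length) || length <= 0)
    stop("section '", name, "': length must be a positive number (um)")
  if (!is.numeric(diameter) || !(base::length(diameter) %in% c(1L, 2L)) ||
      any(!is.finite(diameter)) || any(diameter <= 0))
    stop("section '", name, "': diameter must be positive (um), scalar or c(proximal, distal)")
  nseg <- as.integer(nseg)
  if (is.na(nseg) || nseg < 1L)
    stop("section '", name, "': nseg must be a positive integer")
  if (!is.finite(Ra) || Ra <= 0) stop("section '", name, "': Ra must be > 0 (ohm cm)")
  if (!is.finite(Cm) || Cm <= 0) stop("section '", name, "': Cm must be > 0 (uF/cm^2)")
  if (!is.null(parent)) {
    if (is.character(parent)) parent <- list(section = parent, at = "distal")
    if (is.null(parent$at)) parent$at <- "distal"
    if (!parent$at %in% c("proximal", "distal"))
      stop("section '", name, "': parent attachment end must be 'proximal' or 'distal'")
  }
  if (base::length(channels) && inherits(channels, "hh_channel"))
    channels <- list(channels)
  structure(
    list(name = name, length = length,
         diam_prox = diameter[[1L]],
         diam_dist = diameter[[base::length(diameter)]],
         nseg = nseg, Ra = Ra, Cm = Cm,
         channels = channels, parent = parent),
    class = "hh_section")
}

# Topologically order sections so every parent precedes its children; errors
# on cycles, missing parents, or multiple roots.
order_sections <- function(sections) {
  nms <- vapply(sections, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate section names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  parents <- vapply(sections, function(s)
    if (is.null(s$parent)) NA_character_ else s$parent$section, "")
  roots <- which(is.na(parents))
  if (length(roots) == 0L) stop("no root section (every section has a parent)")
  if (length(roots) > 1L) stop("multiple root sections: ",
                               paste(nms[roots], collapse = ", "))
  missing <- setdiff(parents[!is.na(parents)], nms)
  if (length(missing)) stop("parent section not found: ",
                            paste(missing, collapse = ", "))
  ord <- integer(0)
  placed <- logical(length(sections))
  remaining <- seq_along(sections)
  while (length(remaining)) {
    ready <- remaining[is.na(parents[remaining]) |
                         parents[remaining] %in% nms[placed]]
    if (!length(ready)) stop("cycle detected in section parent relation")
    ord <- c(ord, ready)
    placed[ready] <- TRUE
    remaining <- setdiff(remaining, ready)
  }
  sections[ord]
}

#' Discretize a tree of sections into a Hines-ordered compartment grid
#'
#' Each section of length L with `nseg` compartments contributes `nseg` nodes
#' of length step `dx = L/nseg`, with the membrane potential evaluated at the
#' compartment centers (normalized positions `(k + 0.5)/nseg`). Nodes are
#' numbered so that every node's parent has a smaller index (the ordering the
#' parent-vector Hines solver requires): sections are laid out in topological
#' order and compartments within a section are chained consecutively. The
#' first node of a child section attaches to the node nearest the declared
#' attachment end of its parent section (distal end: the parent's last node;
#' proximal end: its first). Sealed ends (zero axial current at terminals)
#' are realized simply by the absence of any coupling beyond terminal nodes.
#'
#' Radii are interpolated linearly for tapered sections; in addition to the
#' center radius of each node, the radii at the two compartment interfaces
#' are recorded, since the axial coupling coefficients use the interface
#' cross-section.
#'
#' @param sections A list of [section()] objects forming a valid tree (one
#'   root, acyclic parent relation), or a single section.
#' @return An object of class `"hh_grid"`: a list with `n_nodes`, the 0-based
#'   parent vector `parent` (root = -1), per-node `radius`, `radius_prox`,
#'   `radius_dist` (um), `dx` (um), `area` (lateral area, um^2), `Ra`, `Cm`,
#'   `section_of` (section label per node), `node_position` (normalized
#'   center position in the section), `first_node`/`last_node` per section,
#'   and the ordered `sections` list.
#' @examples
#' g <- build_grid(section("axon", length = 100, diameter = 2, nseg = 5))
#' g$parent  # -1 0 1 2 3
#' @export
build_grid <- function(sections) {
  if (inherits(sections, "hh_section")) sections <- list(sections)
  sections <- order_sections(sections)
  nms <- vapply(sections, `[[`, "", "name")
  nseg <- vapply(sections, `[[`, 1L, "nseg")
  n <- sum(nseg)
  first <- cumsum(c(0L, nseg[-length(nseg)]))  # 0-based first node per section
  last <- first + nseg - 1L

  parent <- integer(n)
  radius <- radius_prox <- radius_dist <- dx <- Ra <- Cm <- numeric(n)
  section_of <- character(n)
  node_position <- numeric(n)

  for (s in seq_along(sections)) {
    sec <- sections[[s]]
    k <- seq_len(sec$nseg) - 1L                 # 0-based within section
    idx <- first[s] + k + 1L                    # 1-based into vectors
    pos_c <- (k + 0.5) / sec$nseg
    rp <- sec$diam_prox / 2; rd <- sec$diam_dist / 2
    radius[idx] <- rp + (rd - rp) * pos_c
    radius_prox[idx] <- rp + (rd - rp) * (k / sec$nseg)
    radius_dist[idx] <- rp + (rd - rp) * ((k + 1) / sec$nseg)
    dx[idx] <- sec$length / sec$nseg
    Ra[idx] <- sec$Ra
    Cm[idx] <- sec$Cm
    section_of[idx] <- sec$name
    node_position[idx] <- pos_c
    # chain within the section
    parent[idx] <- first[s] + k - 1L
    if (is.null(sec$parent)) {
      parent[first[s] + 1L] <- -1L
    } else {
      ps <- match(sec$parent$section, nms)
      parent[first[s] + 1L] <-
        if (sec$parent$at == "distal") last[ps] else first[ps]
    }
  }

  grid <- structure(
    list(n_nodes = n, parent = parent,
         radius = radius, radius_prox = radius_prox, radius_dist = radius_dist,
         dx = dx, area = 2 * pi * radius * dx, Ra = Ra, Cm = Cm,
         section_of = section_of, node_position = node_position,
         first_node = stats::setNames(first, nms),
         last_node = stats::setNames(last, nms),
         sections = sections),
    class = "hh_grid")
  rep_ <- validate_grid(grid)
  if (length(rep_)) stop("invalid grid: ", paste(rep_, collapse = "; "))
  grid
}

#' Diagnose structural problems in a compartment grid
#'
#' Pure diagnostic: checks the Hines ordering (`parent[i] < i` for every
#' non-root node), that exactly one root exists, that the parent relation is
#' in range, and that geometry entries are positive and finite.
#'
#' @param grid An `"hh_grid"` object (or any list with compatible fields).
#' @return A character vector of human-readable violation messages; empty
#'   (`character(0)`) iff the grid invariants hold.
#' @export
validate_grid <- function(grid) {
  out <- character(0)
  n <- grid$n_nodes
  p <- grid$parent
  if (length(p) != n) out <- c(out, sprintf("parent vector length %d != n_nodes %d", length(p), n))
  roots <- which(p == -1L)
  if (length(roots) != 1L)
    out <- c(out, sprintf("expected exactly 1 root, found %d", length(roots)))
  bad <- which(p >= seq_len(n) - 1L & p != -1L)  # p[i] >= i (0-based)
  for (i in bad) out <- c(out, sprintf("Hines ordering violation at node %d (parent %d)", i - 1L, p[i]))
  oob <- which(p < -1L | p >= n)
  for (i in oob) out <- c(out, sprintf("parent index out of range at node %d", i - 1L))
  for (fld in c("radius", "dx", "area")) {
    v <- grid[[fld]]
    if (any(!is.finite(v)) || any(v <= 0))
      out <- c(out, sprintf("non-positive or non-finite %s", fld))
  }
  out
}

#' @export
print.hh_grid <- function(x, ...) {
  cat(sprintf("<hh_grid> %d nodes, %d sections (%s)\n", x$n_nodes,
              length(x$sections),
              paste(vapply(x$sections, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}
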
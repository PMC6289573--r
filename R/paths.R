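#' Percentage of a neuron's synaptic connections made with a partner set
#'
#' Synaptic connections between `neuron` and `partner_set` in the given
#' direction, as a percentage of the neuron's total connections in that
#' direction (polyadic expansion: each postsynaptic site counts as one
#' connection). Undefined (returns `NA` with a warning) when the neuron has
#' no connections in that direction.
#'
#' @param edges Edge list from [build_graph()].
#' @param neuron Neuron id.
#' @param partner_set Character vector of partner ids.
#' @param direction `"outgoing"` or `"incoming"`.
#' @return Percentage in \[0, 100\], or `NA`.
#' @export
percent_synaptic_connections <- function(edges, neuron, partner_set,
                                         direction = c("outgoing", "incoming")) {
  direction <- match.arg(direction)
  assert_cols(edges, c("pre", "post", "weight"), "edge list")
  neuron <- as.character(neuron)
  partner_set <- as.character(partner_set)
  if (direction == "outgoing") {
    own <- edges[edges$pre == neuron, ]
    part <- own[own$post %in% partner_set, ]
  } else {
    own <- edges[edges$post == neuron, ]
    part <- own[own$pre %in% partner_set, ]
  }
  total <- sum(own$weight)
  if (total == 0) {
    warn(sprintf("neuron %s has no %s connections; percentage undefined", neuron, direction))
    return(NA_real_)
  }
  100 * sum(part$weight) / total
}

#' Ranking index of a synaptic connection
#'
#' The synapse count of the connection src -> tgt divided by the strongest
#' incoming connection of tgt; 1.0 marks the strongest input among all
#' inputs to the target.
#'
#' @param edges Edge list from [build_graph()].
#' @param src,tgt Neuron ids; the edge src -> tgt must exist.
#' @return Value in (0, 1].
#' @export
ranking_index <- function(edges, src, tgt) {
  assert_cols(edges, c("pre", "post", "weight"), "edge list")
  src <- as.character(src)
  tgt <- as.character(tgt)
  incoming <- edges[edges$post == tgt, ]
  if (nrow(incoming) == 0L) abort(sprintf("neuron %s has no incoming connections", tgt))
  w <- incoming$weight[incoming$pre == src]
  if (length(w) == 0L) abort(sprintf("no connection %s -> %s", src, tgt))
  w / max(incoming$weight)
}

#' Remove edges below a synaptic threshold
#'
#' @param edges Edge list from [build_graph()].
#' @param threshold Minimum synapse count an edge must carry to survive
#'   (default 2, the reference analysis's threshold).
#' @return Filtered edge list (nodes simply disappear from the edge list if
#'   they lose all edges).
#' @export
threshold_graph <- function(edges, threshold = 2) {
  assert_cols(edges, c("pre", "post", "weight"), "edge list")
  if (threshold < 1) abort("`threshold` must be at least 1")
  edges[edges$weight >= threshold, , drop = FALSE]
}

#' Enumerate 1/2/3-hop paths from sensory sources to an output neuron
#'
#' Direct (1-hop) connections plus indirect routes through one (2-hop) or
#' two (3-hop) interneurons, on the graph thresholded at `threshold`
#' synapses per directed edge. Paths are simple (no repeated neurons), and
#' only neurons of class `"interneuron"` may serve as intermediates. 3-hop
#' enumeration works backward from the target's direct ( >= threshold )
#' upstream interneurons; with a uniform per-edge threshold this
#' direct-upstream restriction is implied by path validity, and
#' `restrict_3hop = FALSE` (kept for explicitness) enumerates the identical
#' set.
#'
#' @param edges Edge list from [build_graph()].
#' @param annotations Annotation table (`neuron_id`, `class`).
#' @param sources Character vector of source (sensory) neuron ids; must not
#'   contain the target.
#' @param target Output neuron id.
#' @param threshold Per-edge synapse threshold (default 2).
#' @param max_hops Maximum path length, 1-3 (default 3).
#' @param restrict_3hop Restrict the 3-hop frontier to the target's direct
#'   upstream set (default `TRUE`; see above).
#' @return An object of class `path_set`; `tidy()` returns the path table
#'   (`hops`, `source`, `i1`, `i2`, `target`, `w1`, `w2`, `w3`).
#' @export
enumerate_paths <- function(edges, annotations, sources, target, threshold = 2,
                            max_hops = 3, restrict_3hop = TRUE) {
  assert_cols(edges, c("pre", "post", "weight"), "edge list")
  assert_cols(annotations, c("neuron_id", "class"), "annotations")
  sources <- as.character(sources)
  target <- as.character(target)
  if (target %in% sources) abort("target must not be among the sources")
  if (!(max_hops %in% 1:3)) abort("`max_hops` must be 1, 2 or 3")

  g <- threshold_graph(edges, threshold)
  g <- g[g$pre != g$post, , drop = FALSE] # never traverse autapses
  cls <- stats::setNames(as.character(annotations$class), as.character(annotations$neuron_id))
  inter <- names(cls)[cls == "interneuron"]
  inter <- setdiff(inter, c(sources, target))

  p1 <- g %>%
    dplyr::filter(.data$pre %in% sources, .data$post == target) %>%
    dplyr::transmute(
      hops = 1L, source = .data$pre, i1 = NA_character_, i2 = NA_character_,
      target = .data$post, w1 = .data$weight, w2 = NA_integer_, w3 = NA_integer_
    )

  p2 <- p3 <- p1[0, ]
  if (max_hops >= 2L) {
    leg1 <- g %>%
      dplyr::filter(.data$pre %in% sources, .data$post %in% inter) %>%
      dplyr::select(source = "pre", i1 = "post", w1 = "weight")
    leg2 <- g %>%
      dplyr::filter(.data$pre %in% inter, .data$post == target) %>%
      dplyr::select(i1 = "pre", w2 = "weight")
    p2 <- leg1 %>%
      dplyr::inner_join(leg2, by = "i1") %>%
      dplyr::transmute(
        hops = 2L, .data$source, .data$i1, i2 = NA_character_, target = target,
        .data$w1, .data$w2, w3 = NA_integer_
      )
  }
  if (max_hops >= 3L) {
    # Backward traversal: U1 = target's direct >= threshold interneuron
    # upstream; second interneurons are drawn from U1, first interneurons
    # from U1's upstream.
    u1 <- g$pre[g$post == target & g$pre %in% inter]
    frontier2 <- if (restrict_3hop) u1 else inter
    leg3 <- g %>%
      dplyr::filter(.data$pre %in% frontier2, .data$post == target) %>%
      dplyr::select(i2 = "pre", w3 = "weight")
    leg2 <- g %>%
      dplyr::filter(.data$pre %in% inter, .data$post %in% leg3$i2) %>%
      dplyr::select(i1 = "pre", i2 = "post", w2 = "weight")
    leg1 <- g %>%
      dplyr::filter(.data$pre %in% sources, .data$post %in% leg2$i1) %>%
      dplyr::select(source = "pre", i1 = "post", w1 = "weight")
    p3 <- leg1 %>%
      dplyr::inner_join(leg2, by = "i1", relationship = "many-to-many") %>%
      dplyr::inner_join(leg3, by = "i2") %>%
      dplyr::filter(.data$i1 != .data$i2) %>%
      dplyr::transmute(
        hops = 3L, .data$source, .data$i1, .data$i2, target = target,
        .data$w1, .data$w2, .data$w3
      )
  }

  paths <- dplyr::bind_rows(p1, p2, p3) %>%
    dplyr::arrange(.data$hops, .data$source, .data$i1, .data$i2)
  structure(
    list(
      paths = paths,
      sources = sources,
      target = target,
      threshold = threshold,
      max_hops = max_hops,
      restrict_3hop = restrict_3hop,
      classes = cls
    ),
    class = "path_set"
  )
}

#' @export
print.path_set <- function(x, ...) {
  tab <- table(factor(x$paths$hops, levels = 1:3))
  cat(sprintf(
    "<path_set> %s -> %s (threshold %d): %d x 1-hop, %d x 2-hop, %d x 3-hop\n",
    sprintf("%d source(s)", length(x$sources)), x$target, x$threshold,
    tab[["1"]], tab[["2"]], tab[["3"]]
  ))
  invisible(x)
}

#' @export
tidy.path_set <- function(x, ...) {
  x$paths
}

#' @export
glance.path_set <- function(x, ...) {
  tab <- table(factor(x$paths$hops, levels = 1:3))
  tibble(
    n_sources = length(x$sources),
    target = x$target,
    threshold = x$threshold,
    n_1hop = as.integer(tab[["1"]]),
    n_2hop = as.integer(tab[["2"]]),
    n_3hop = as.integer(tab[["3"]]),
    n_interneurons = dplyr::n_distinct(stats::na.omit(c(x$paths$i1, x$paths$i2)))
  )
}

#' Assign interneurons to circuit layers relative to one output neuron
#'
#' Backward traversal from the target at a fixed synaptic threshold:
#' sensory neurons with a direct >= threshold edge onto the target are
#' `L1-source`; interneurons directly presynaptic to the target that sit on
#' a valid 2-hop path (i.e. also receive >= threshold input from a source)
#' are `L2`; interneurons one step further upstream (a >= threshold edge
#' onto the direct-upstream interneuron set, but no direct edge onto the
#' target) form layer 3, split into `L3a` (receive >= threshold input from
#' at least one sensory source) and `L3b` (receive none); the target is
#' `output`.
#'
#' @param edges Edge list from [build_graph()].
#' @param annotations Annotation table (`neuron_id`, `class`).
#' @param sensory Character vector of sensory neuron ids.
#' @param target Output neuron id.
#' @param threshold Per-edge synapse threshold (default 2).
#' @return Tibble with columns `neuron_id`, `layer` (one of `L1-source`,
#'   `L2`, `L3a`, `L3b`, `output`).
#' @export
assign_layers <- function(edges, annotations, sensory, target, threshold = 2) {
  assert_cols(edges, c("pre", "post", "weight"), "edge list")
  sensory <- as.character(sensory)
  target <- as.character(target)
  g <- threshold_graph(edges, threshold)
  g <- g[g$pre != g$post, , drop = FALSE]
  cls <- stats::setNames(as.character(annotations$class), as.character(annotations$neuron_id))
  inter <- setdiff(names(cls)[cls == "interneuron"], c(sensory, target))

  u1 <- unique(g$pre[g$post == target & g$pre %in% inter])
  has_sensory_input <- function(n) any(g$pre %in% sensory & g$post == n)
  l1 <- unique(g$pre[g$post == target & g$pre %in% sensory])
  l2 <- u1[vapply(u1, has_sensory_input, logical(1))]
  l3 <- setdiff(unique(g$pre[g$post %in% u1 & g$pre %in% inter]), c(u1, target))
  l3a <- l3[vapply(l3, has_sensory_input, logical(1))]
  l3b <- setdiff(l3, l3a)

  dplyr::bind_rows(
    tibble(neuron_id = l1, layer = "L1-source"),
    tibble(neuron_id = l2, layer = "L2"),
    tibble(neuron_id = l3a, layer = "L3a"),
    tibble(neuron_id = l3b, layer = "L3b"),
    tibble(neuron_id = target, layer = "output")
  ) %>%
    dplyr::arrange(factor(.data$layer, levels = c("L1-source", "L2", "L3a", "L3b", "output")), .data$neuron_id)
}

#' Divergence and convergence statistics of a path set
#'
#' From the 2-hop paths: for each interneuron, the convergence degree (how
#' many distinct sources route through it to the target); for each source,
#' the divergence (how many distinct interneuron routes it has to the
#' target).
#'
#' @param paths A `path_set` from [enumerate_paths()].
#' @return An object of class `convergence_report`: list with tibbles
#'   `convergence` (`interneuron`, `degree`) and `divergence` (`source`,
#'   `divergence`).
#' @export
convergence_divergence <- function(paths) {
  stopifnot(inherits(paths, "path_set"))
  p2 <- paths$paths[paths$paths$hops == 2L, ]
  conv <- p2 %>%
    dplyr::distinct(.data$i1, .data$source) %>%
    dplyr::count(interneuron = .data$i1, name = "degree") %>%
    dplyr::arrange(dplyr::desc(.data$degree), .data$interneuron)
  div <- p2 %>%
    dplyr::distinct(.data$source, .data$i1) %>%
    dplyr::count(source = .data$source, name = "divergence") %>%
    dplyr::arrange(dplyr::desc(.data$divergence), .data$source)
  structure(
    list(convergence = conv, divergence = div, target = paths$target),
    class = "convergence_report"
  )
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf(
    "<convergence_report> target %s: %d interneuron(s), max degree %s; %d source(s), max divergence %s\n",
    x$target, nrow(x$convergence),
    if (nrow(x$convergence)) max(x$convergence$degree) else "-",
    nrow(x$divergence),
    if (nrow(x$divergence)) max(x$divergence$divergence) else "-"
  ))
  invisible(x)
}

#' @export
tidy.convergence_report <- function(x, ...) {
  dplyr::full_join(
    dplyr::rename(x$convergence, neuron_id = "interneuron"),
    dplyr::rename(x$divergence, neuron_id = "source"),
    by = "neuron_id"
  )
}

#' Final common interneurons between an upstream set and output neurons
#'
#' Interneurons that receive >= threshold synapses from at least one member
#' of `upstream_set` (e.g. mushroom body output neurons) and contact at
#' least one member of `output_set` with >= threshold synapses — the relay
#' points through which a modulatory system feeds the same output neurons
#' as the sensory paths. Each row carries the interneuron's layer relative
#' to the output it contacts.
#'
#' @param edges Edge list from [build_graph()].
#' @param annotations Annotation table (`neuron_id`, `class`).
#' @param upstream_set,output_set Disjoint character vectors of neuron ids.
#' @param sensory Sensory neuron ids (for the layer labels).
#' @param threshold Per-edge synapse threshold (default 2).
#' @return Tibble with `interneuron`, `output`, `layer`, `n_upstream`
#'   (number of upstream_set members contacting it at >= threshold).
#' @export
common_interneurons <- function(edges, annotations, upstream_set, output_set,
                                sensory, threshold = 2) {
  upstream_set <- as.character(upstream_set)
  output_set <- as.character(output_set)
  if (length(intersect(upstream_set, output_set)) > 0L) {
    abort("`upstream_set` and `output_set` must be disjoint")
  }
  g <- threshold_graph(edges, threshold)
  cls <- stats::setNames(as.character(annotations$class), as.character(annotations$neuron_id))
  inter <- names(cls)[cls == "interneuron"]

  from_up <- g %>%
    dplyr::filter(.data$pre %in% upstream_set, .data$post %in% inter) %>%
    dplyr::count(interneuron = .data$post, name = "n_upstream")
  to_out <- g %>%
    dplyr::filter(.data$pre %in% inter, .data$post %in% output_set) %>%
    dplyr::distinct(interneuron = .data$pre, output = .data$post)
  ci <- dplyr::inner_join(from_up, to_out, by = "interneuron")
  if (nrow(ci) == 0L) {
    return(tibble(
      interneuron = character(), output = character(),
      layer = character(), n_upstream = integer()
    ))
  }
  layers <- purrr::map_dfr(unique(ci$output), function(o) {
    assign_layers(edges, annotations, sensory, o, threshold) %>%
      dplyr::mutate(output = o)
  })
  ci %>%
    dplyr::left_join(layers, by = c(interneuron = "neuron_id", output = "output")) %>%
    dplyr::transmute(
      .data$interneuron, .data$output,
      layer = dplyr::coalesce(.data$layer, "unlayered"), .data$n_upstream
    ) %>%
    dplyr::arrange(.data$interneuron, .data$output)
}

#' Fraction of compartment members engaged in a connection motif
#'
#' For each compartment, the percentage of member neurons with at least one
#' qualifying >= threshold edge: direct output onto the output set
#' (`"monosynaptic-to-outputs"`, the monosynaptic reflex motif), or a
#' connection in either direction with another sensory member of the same
#' compartment (`"intra-compartment-sensory"`, axo-axonic inter-sensory
#' contacts).
#'
#' @param assignment Assignment tibble (`neuron_id`, `cluster`) or
#'   `compartment_clustering` object.
#' @param edges Edge list from [build_graph()].
#' @param relation Which motif qualifies (see above).
#' @param threshold Per-edge synapse threshold (default 2).
#' @param output_set Output neuron ids (required for
#'   `"monosynaptic-to-outputs"`).
#' @return Tibble with `cluster`, `n`, `n_connected`, `percent`.
#' @export
fraction_neurons_connected <- function(assignment, edges,
                                       relation = c("monosynaptic-to-outputs", "intra-compartment-sensory"),
                                       threshold = 2, output_set = NULL) {
  relation <- match.arg(relation)
  if (inherits(assignment, "compartment_clustering")) assignment <- assignment$assignment
  assert_cols(assignment, c("neuron_id", "cluster"), "assignment")
  g <- threshold_graph(edges, threshold)
  g <- g[g$pre != g$post, , drop = FALSE]
  assignment <- dplyr::mutate(assignment, neuron_id = as.character(.data$neuron_id))

  qualifies <- switch(relation,
    "monosynaptic-to-outputs" = {
      if (is.null(output_set)) abort("`output_set` is required for relation \"monosynaptic-to-outputs\"")
      output_set <- as.character(output_set)
      function(member, members) any(g$pre == member & g$post %in% output_set)
    },
    "intra-compartment-sensory" = {
      function(member, members) {
        others <- setdiff(members, member)
        any(g$pre == member & g$post %in% others) ||
          any(g$post == member & g$pre %in% others)
      }
    }
  )
  assignment %>%
    dplyr::group_by(.data$cluster) %>%
    dplyr::summarise(
      n = dplyr::n(),
      n_connected = sum(vapply(
        .data$neuron_id,
        function(m) qualifies(m, .data$neuron_id), logical(1)
      )),
      .groups = "drop"
    ) %>%
    dplyr::mutate(percent = 100 * .data$n_connected / .data$n)
}
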
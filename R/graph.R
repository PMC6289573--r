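#' Validate a skeleton node table
#'
#' A skeleton is a rooted tree of treenodes: exactly one root (missing
#' `parent_id`), acyclic parent links, and every non-root parent resolving to
#' a node of the same skeleton. The report carries the individual findings
#' rather than stopping at the first problem, so malformed reconstructions
#' can be triaged in bulk.
#'
#' @param skeleton A data frame with columns `node_id`, `parent_id` (`NA` for
#'   the root), and coordinates `x`, `y`, `z` in nm.
#' @return A list of class `skeleton_validation` with elements `n_nodes`,
#'   `n_roots`, `root_ids`, `orphan_nodes` (nodes whose parent id does not
#'   exist), `has_cycle`, `connected`, `finite_positions` and the overall
#'   `valid` flag.
#' @examples
#' sk <- tibble::tibble(
#'   node_id = 1:3, parent_id = c(NA, 1L, 2L),
#'   x = c(0, 1000, 2000), y = 0, z = 0
#' )
#' validate_skeleton(sk)$valid
#' @export
validate_skeleton <- function(skeleton) {
  assert_cols(skeleton, c("node_id", "parent_id", "x", "y", "z"), "skeleton")
  if (nrow(skeleton) < 1L) abort("skeleton must contain at least one node")
  ids <- skeleton$node_id
  if (anyDuplicated(ids)) abort("skeleton has duplicated node ids")

  is_root <- is.na(skeleton$parent_id)
  root_ids <- ids[is_root]
  orphans <- ids[!is_root & !(skeleton$parent_id %in% ids)]

  # Parent links among known nodes, checked for cycles / connectivity as a
  # directed child -> parent graph.
  known <- !is_root & (skeleton$parent_id %in% ids)
  has_cycle <- FALSE
  connected <- TRUE
  if (any(known)) {
    g <- igraph::graph_from_data_frame(
      data.frame(
        from = as.character(ids[known]),
        to = as.character(skeleton$parent_id[known])
      ),
      directed = TRUE,
      vertices = data.frame(name = as.character(ids))
    )
    has_cycle <- !igraph::is_dag(g)
    connected <- igraph::count_components(g, mode = "weak") == 1L
  } else {
    connected <- nrow(skeleton) == 1L
  }
  if (any(!is_root & skeleton$parent_id == ids, na.rm = TRUE)) has_cycle <- TRUE

  finite_positions <- all(is.finite(as.matrix(skeleton[, c("x", "y", "z")])))

  out <- list(
    n_nodes = nrow(skeleton),
    n_roots = length(root_ids),
    root_ids = root_ids,
    orphan_nodes = orphans,
    has_cycle = has_cycle,
    connected = connected,
    finite_positions = finite_positions,
    valid = length(root_ids) == 1L && length(orphans) == 0L &&
      !has_cycle && connected && finite_positions
  )
  class(out) <- "skeleton_validation"
  out
}

#' @export
print.skeleton_validation <- function(x, ...) {
  cat(sprintf(
    "<skeleton_validation> %d nodes, %d root(s), %d orphan(s), cycle: %s, connected: %s -> %s\n",
    x$n_nodes, x$n_roots, length(x$orphan_nodes),
    x$has_cycle, x$connected, if (x$valid) "VALID" else "INVALID"
  ))
  invisible(x)
}

#' Build the directed synaptic graph from a polyadic connector table
#'
#' One connector is a single presynaptic release site contacting one or more
#' postsynaptic neurites; each postsynaptic site counts as one synaptic
#' connection. A connector with m postsynaptic rows therefore contributes m
#' units of edge weight, so the total edge weight of the graph equals the
#' number of rows of the connector table.
#'
#' @param connectors A data frame with one row per postsynaptic site and
#'   columns `connector_id`, `pre_neuron`, `post_neuron` (positions and other
#'   columns are ignored here).
#' @return A tibble edge list with columns `pre`, `post` and integer
#'   `weight`, sorted by `pre`, `post`.
#' @examples
#' con <- tibble::tibble(
#'   connector_id = c(1, 1, 2), pre_neuron = "A",
#'   post_neuron = c("B", "C", "B")
#' )
#' build_graph(con)
#' @export
build_graph <- function(connectors) {
  assert_cols(connectors, c("connector_id", "pre_neuron", "post_neuron"), "connector table")
  if (nrow(connectors) == 0L) {
    return(tibble(pre = character(), post = character(), weight = integer()))
  }
  bad <- connectors$connector_id[is.na(connectors$post_neuron)]
  if (length(bad) > 0L) {
    abort(sprintf(
      "connector(s) without postsynaptic site: %s",
      paste(unique(bad), collapse = ", ")
    ))
  }
  multi_pre <- connectors %>%
    dplyr::distinct(.data$connector_id, .data$pre_neuron) %>%
    dplyr::count(.data$connector_id) %>%
    dplyr::filter(.data$n > 1L)
  if (nrow(multi_pre) > 0L) {
    abort(sprintf(
      "connector(s) with more than one presynaptic neuron: %s",
      paste(multi_pre$connector_id, collapse = ", ")
    ))
  }
  connectors %>%
    dplyr::count(
      pre = as.character(.data$pre_neuron),
      post = as.character(.data$post_neuron),
      name = "weight"
    ) %>%
    dplyr::arrange(.data$pre, .data$post)
}

#' Summarise synaptic connections between annotated neuron classes
#'
#' Tallies edge weight over ordered (presynaptic class, postsynaptic class)
#' pairs and expresses each cell as a fraction of its source class's total
#' output, e.g. to quantify how much of the sensory neurons' output lands on
#' other sensory neurons versus interneurons or motor neurons.
#'
#' @param edges Edge list from [build_graph()].
#' @param annotations Data frame with columns `neuron_id` and `class`.
#' @return Tibble with `pre_class`, `post_class`, `n` (synaptic connections)
#'   and `fraction` (of the source class's outgoing total).
#' @export
class_to_class_summary <- function(edges, annotations) {
  assert_cols(edges, c("pre", "post", "weight"), "edge list")
  assert_cols(annotations, c("neuron_id", "class"), "annotations")
  cls <- stats::setNames(
    as.character(annotations$class),
    as.character(annotations$neuron_id)
  )
  nodes <- unique(c(edges$pre, edges$post))
  missing <- nodes[!(nodes %in% names(cls))]
  if (length(missing) > 0L) {
    abort(sprintf(
      "unannotated neuron(s) in graph: %s",
      paste(missing, collapse = ", ")
    ))
  }
  edges %>%
    dplyr::mutate(
      pre_class = unname(cls[.data$pre]),
      post_class = unname(cls[.data$post])
    ) %>%
    dplyr::count(.data$pre_class, .data$post_class,
      wt = .data$weight, name = "n"
    ) %>%
    dplyr::group_by(.data$pre_class) %>%
    dplyr::mutate(fraction = .data$n / sum(.data$n)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$pre_class, .data$post_class)
}
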
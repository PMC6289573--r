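#' Serialize a compartment dendrogram as Newick text
#'
#' Leaves are neuron ids; the depth of every leaf below a merge equals that
#' merge's cophenetic height, so branch lengths are merge-height differences
#' and the tree is ultrametric. A two-leaf tree merged at height 0.3 is
#' written as `(a:0.3,b:0.3);`.
#'
#' @param x A [cluster_compartments()] result, an `hclust` object, or a
#'   single leaf label (character) for the degenerate one-neuron tree.
#' @param path Optional file path; when given the Newick string is written
#'   there.
#' @return The Newick string (invisibly when `path` is given).
#' @export
write_dendrogram_newick <- function(x, path = NULL) {
  if (inherits(x, "compartment_clustering")) x <- x$hclust
  if (is.character(x) && length(x) == 1L) {
    nwk <- paste0(x, ";")
  } else if (inherits(x, "hclust")) {
    nwk <- newick_from_hclust(x)
  } else {
    abort("`x` must be a compartment_clustering, hclust, or single label")
  }
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

newick_from_hclust <- function(hc) {
  labels <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1L))
  fmt <- function(v) sprintf("%.10g", v)
  branch <- function(child, h_parent) {
    if (child < 0L) {
      paste0(labels[-child], ":", fmt(h_parent))
    } else {
      paste0(
        "(", inner(child), "):",
        fmt(h_parent - hc$height[child])
      )
    }
  }
  inner <- function(i) {
    h <- hc$height[i]
    paste0(branch(hc$merge[i, 1L], h), ",", branch(hc$merge[i, 2L], h))
  }
  paste0("(", inner(nrow(hc$merge)), ");")
}

#' Export an enumerated path set as GraphML
#'
#' Nodes are the neurons appearing on at least one path, attributed with
#' their class and (optionally) path layer; edges are the distinct
#' consecutive hops, weighted by synaptic-connection count. An empty path
#' set produces a document with zero nodes.
#'
#' @param paths A `path_set` from [enumerate_paths()].
#' @param path Output file path.
#' @param layers Optional layer assignment tibble (`neuron_id`, `layer`)
#'   from [assign_layers()].
#' @return `path`, invisibly.
#' @export
write_paths_graphml <- function(paths, path, layers = NULL) {
  stopifnot(inherits(paths, "path_set"))
  g <- paths_to_igraph(paths, layers)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

paths_to_igraph <- function(paths, layers = NULL) {
  el <- path_edges(paths)
  nodes <- unique(c(el$from, el$to))
  cls <- paths$classes
  layer_of <- stats::setNames(character(0), character(0))
  if (!is.null(layers)) {
    layer_of <- stats::setNames(as.character(layers$layer), as.character(layers$neuron_id))
  }
  vdf <- data.frame(
    name = nodes,
    class = ifelse(nodes %in% names(cls), unname(cls[nodes]), ""),
    layer = ifelse(nodes %in% names(layer_of), unname(layer_of[nodes]), ""),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(el, directed = TRUE, vertices = vdf)
}

# Distinct consecutive hops of a path set as a weighted edge list.
path_edges <- function(paths) {
  p <- paths$paths
  if (nrow(p) == 0L) {
    return(data.frame(
      from = character(), to = character(), weight = integer(),
      stringsAsFactors = FALSE
    ))
  }
  hops <- dplyr::bind_rows(
    p %>% dplyr::filter(.data$hops == 1L) %>%
      dplyr::transmute(from = .data$source, to = .data$target, weight = .data$w1),
    p %>% dplyr::filter(.data$hops == 2L) %>%
      dplyr::transmute(from = .data$source, to = .data$i1, weight = .data$w1),
    p %>% dplyr::filter(.data$hops == 2L) %>%
      dplyr::transmute(from = .data$i1, to = .data$target, weight = .data$w2),
    p %>% dplyr::filter(.data$hops == 3L) %>%
      dplyr::transmute(from = .data$source, to = .data$i1, weight = .data$w1),
    p %>% dplyr::filter(.data$hops == 3L) %>%
      dplyr::transmute(from = .data$i1, to = .data$i2, weight = .data$w2),
    p %>% dplyr::filter(.data$hops == 3L) %>%
      dplyr::transmute(from = .data$i2, to = .data$target, weight = .data$w3)
  )
  as.data.frame(dplyr::distinct(hops))
}
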
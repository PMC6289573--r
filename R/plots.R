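# ggplot2 visualisations for the main result types.

#' Plot a compartment clustering dendrogram
#'
#' Dendrogram on the similarity scale (1 - merge height) with leaves
#' coloured by assigned compartment and the score cut marked.
#'
#' @param object A `compartment_clustering` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.compartment_clustering <- function(object, ...) {
  seg <- dendrogram_segments(object$hclust)
  leaves <- tibble(
    x = seq_along(object$hclust$order),
    label = object$hclust$labels[object$hclust$order]
  ) %>%
    dplyr::left_join(object$assignment, by = c(label = "neuron_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = 1 - .data$y, yend = 1 - .data$yend),
      linewidth = 0.3
    ) +
    ggplot2::geom_hline(yintercept = object$score_cut, linetype = "dashed", colour = "red") +
    ggplot2::geom_point(
      data = leaves,
      ggplot2::aes(x = .data$x, y = 1, colour = factor(.data$cluster)),
      size = 1.5
    ) +
    ggplot2::scale_y_continuous("similarity score", limits = c(NA, 1.02)) +
    ggplot2::labs(x = NULL, colour = "compartment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.grid.major.x = ggplot2::element_blank()
    )
}

# Segment coordinates of an hclust dendrogram (leaf order on x, merge
# heights on y).
dendrogram_segments <- function(hc) {
  n <- length(hc$order)
  xpos <- numeric(n + nrow(hc$merge))
  leaf_x <- stats::setNames(seq_len(n), hc$order)
  node_x <- function(id) if (id < 0L) leaf_x[[as.character(-id)]] else xpos[n + id]
  node_h <- function(id) if (id < 0L) 0 else hc$height[id]
  segs <- list()
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1L]
    b <- hc$merge[i, 2L]
    xa <- node_x(a)
    xb <- node_x(b)
    h <- hc$height[i]
    xpos[n + i] <- (xa + xb) / 2
    segs[[i]] <- tibble(
      x = c(xa, xb, xa), xend = c(xa, xb, xb),
      y = c(node_h(a), node_h(b), h), yend = c(h, h, h)
    )
  }
  dplyr::bind_rows(segs)
}

#' Plot an enumerated path set as a layered diagram
#'
#' Neurons are placed in columns by their position along the paths (source,
#' first/second interneuron, output); edge width encodes synapse count.
#'
#' @param object A `path_set` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.path_set <- function(object, ...) {
  p <- object$paths
  nodes <- dplyr::bind_rows(
    tibble(neuron_id = unique(p$source), role = "source", depth = 0),
    tibble(neuron_id = unique(stats::na.omit(p$i1)), role = "interneuron", depth = 1),
    tibble(neuron_id = unique(stats::na.omit(p$i2)), role = "interneuron", depth = 2),
    tibble(neuron_id = object$target, role = "output", depth = 3)
  ) %>%
    dplyr::group_by(.data$neuron_id) %>%
    dplyr::summarise(role = .data$role[1L], depth = min(.data$depth), .groups = "drop") %>%
    dplyr::group_by(.data$depth) %>%
    dplyr::mutate(ypos = dplyr::row_number() - (dplyr::n() + 1) / 2) %>%
    dplyr::ungroup()
  el <- path_edges(object) %>%
    dplyr::left_join(nodes, by = c(from = "neuron_id")) %>%
    dplyr::left_join(nodes, by = c(to = "neuron_id"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = el,
      ggplot2::aes(
        x = .data$depth, y = .data$ypos,
        xend = .data$depth_to, yend = .data$ypos_to,
        linewidth = .data$weight
      ),
      alpha = 0.4
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$depth, y = .data$ypos, colour = .data$role),
      size = 3
    ) +
    ggplot2::scale_linewidth_continuous(range = c(0.2, 1.5)) +
    ggplot2::scale_x_continuous(
      breaks = 0:3,
      labels = c("sensory", "interneuron 1", "interneuron 2", "output")
    ) +
    ggplot2::labs(x = NULL, y = NULL, linewidth = "synapses") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}

#' Heatmap of a similarity matrix
#'
#' Rows and columns are ordered by average-linkage clustering of the
#' (symmetrized) matrix so block structure is visible.
#'
#' @param similarity Square similarity matrix with dimnames.
#' @return A ggplot object.
#' @export
plot_similarity_matrix <- function(similarity) {
  sym <- (similarity + t(similarity)) / 2
  sym[is.na(sym)] <- 0
  ord <- average_linkage(1 - sym)$order
  labels <- rownames(similarity)[ord]
  df <- as_tibble(similarity[ord, ord], rownames = "row") %>%
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "score") %>%
    dplyr::mutate(
      row = factor(.data$row, levels = labels),
      col = factor(.data$col, levels = labels)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
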
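#' Convert a similarity matrix to a distance matrix
#'
#' Uses `d = 1 - s`, so similarity 1 maps to distance 0 and a similarity
#' cut-off c corresponds to a dendrogram cut height of `1 - c`. Undefined
#' (`NA`) similarities become the maximal distance 1, with a warning.
#'
#' @param similarity Square numeric matrix in \[0, 1\] with dimnames.
#' @param symmetrize Symmetrize an asymmetric input by averaging with its
#'   transpose; when `FALSE` (default) an asymmetric input is an error.
#' @return Distance matrix (zero diagonal) with the same dimnames.
#' @export
similarity_to_distance <- function(similarity, symmetrize = FALSE) {
  if (!is.matrix(similarity) || nrow(similarity) != ncol(similarity)) {
    abort("`similarity` must be a square matrix")
  }
  if (!isTRUE(all.equal(similarity, t(similarity), tolerance = 1e-8))) {
    if (!symmetrize) abort("similarity matrix is asymmetric; pass symmetrize = TRUE")
    similarity <- (similarity + t(similarity)) / 2
  }
  if (anyNA(similarity)) {
    warn("undefined similarities set to maximal distance 1")
    similarity[is.na(similarity)] <- 0
  }
  rng <- range(similarity)
  if (rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9) {
    abort("similarity values must lie in [0, 1]")
  }
  d <- 1 - similarity
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Thin wrapper around [stats::hclust()] with `method = "average"`, after
#' canonically ordering the labels so the merge sequence is independent of
#' the input row order.
#'
#' @param dist_matrix Square symmetric distance matrix with dimnames, or a
#'   `dist` object.
#' @return An `hclust` object.
#' @export
average_linkage <- function(dist_matrix) {
  if (inherits(dist_matrix, "dist")) dist_matrix <- as.matrix(dist_matrix)
  if (!is.matrix(dist_matrix) || nrow(dist_matrix) != ncol(dist_matrix)) {
    abort("`dist_matrix` must be a square matrix or dist object")
  }
  if (nrow(dist_matrix) < 2L) abort("clustering needs at least two elements")
  labels <- rownames(dist_matrix) %||% as.character(seq_len(nrow(dist_matrix)))
  ord <- order(labels)
  hc <- stats::hclust(stats::as.dist(dist_matrix[ord, ord]), method = "average")
  # UPGMA merge heights are non-decreasing in exact arithmetic, but ties
  # between numerically indistinguishable inter-cluster means can come out
  # microscopically inverted in floating point, which cutree() rejects.
  # Repair sub-tolerance inversions; anything larger is a real error.
  viol <- hc$height - cummax(hc$height)
  if (any(viol < -1e-8)) abort("average-linkage heights decreased beyond tolerance")
  hc$height <- cummax(hc$height)
  hc
}

#' Cut a dendrogram at a similarity threshold
#'
#' Clusters are the merge subtrees whose heights do not exceed
#' `1 - score_cut`: members of a cluster have mean pairwise similarity at or
#' above `score_cut` under the `d = 1 - s` convention. Labels are
#' canonical: clusters are numbered by their lexicographically smallest
#' member id, so the assignment is invariant to leaf input order.
#'
#' @param hc An `hclust` object (distances on the `1 - s` scale).
#' @param score_cut Similarity threshold in \[0, 1\]; the reference
#'   compartment analysis cuts the synapse-similarity dendrogram at 0.06.
#' @return Tibble with columns `neuron_id` and integer `cluster`.
#' @export
cut_dendrogram <- function(hc, score_cut = 0.06) {
  stopifnot(inherits(hc, "hclust"))
  if (score_cut < 0 || score_cut > 1) abort("`score_cut` must lie in [0, 1]")
  raw <- stats::cutree(hc, h = 1 - score_cut)
  canonicalize_assignment(tibble(
    neuron_id = names(raw) %||% as.character(seq_along(raw)),
    cluster = as.integer(raw)
  ))
}

canonicalize_assignment <- function(assignment) {
  key <- assignment %>%
    dplyr::group_by(.data$cluster) %>%
    dplyr::summarise(lead_id = min(.data$neuron_id), .groups = "drop") %>%
    dplyr::arrange(.data$lead_id) %>%
    dplyr::mutate(new = dplyr::row_number())
  assignment %>%
    dplyr::left_join(key[, c("cluster", "new")], by = "cluster") %>%
    dplyr::transmute(.data$neuron_id, cluster = .data$new) %>%
    dplyr::arrange(.data$neuron_id)
}

#' Cluster neurons into compartments from a similarity matrix
#'
#' The full compartment pipeline: (optional) symmetrization, conversion to
#' `1 - s` distances, average-linkage clustering, and a cut at
#' `score_cut`. With the synapse similarity score this is the procedure
#' that delineates the sensory compartments of the feeding connectome.
#'
#' @param similarity Square similarity matrix (e.g. from
#'   [synapse_similarity_matrix()]).
#' @param score_cut Similarity threshold for cluster formation (default
#'   0.06).
#' @param symmetrize Symmetrize an asymmetric matrix first (default `TRUE`).
#' @return An object of class `compartment_clustering` with elements
#'   `hclust`, `assignment` (tibble), `n_clusters`, `score_cut`,
#'   `similarity`.
#' @export
cluster_compartments <- function(similarity, score_cut = 0.06, symmetrize = TRUE) {
  d <- similarity_to_distance(similarity, symmetrize = symmetrize)
  hc <- average_linkage(d)
  assignment <- cut_dendrogram(hc, score_cut)
  structure(
    list(
      hclust = hc,
      assignment = assignment,
      n_clusters = dplyr::n_distinct(assignment$cluster),
      score_cut = score_cut,
      similarity = similarity
    ),
    class = "compartment_clustering"
  )
}

#' @export
print.compartment_clustering <- function(x, ...) {
  cat(sprintf(
    "<compartment_clustering> %d neurons in %d cluster(s) at score cut %.3g\n",
    nrow(x$assignment), x$n_clusters, x$score_cut
  ))
  invisible(x)
}

#' @describeIn cluster_compartments Per-neuron cluster assignment as a tibble.
#' @param x A `compartment_clustering` object.
#' @param ... Unused.
#' @export
tidy.compartment_clustering <- function(x, ...) {
  x$assignment
}

#' @describeIn cluster_compartments One-row model summary.
#' @export
glance.compartment_clustering <- function(x, ...) {
  sizes <- table(x$assignment$cluster)
  tibble(
    n_neurons = nrow(x$assignment),
    n_clusters = x$n_clusters,
    score_cut = x$score_cut,
    largest_cluster = as.integer(max(sizes)),
    smallest_cluster = as.integer(min(sizes)),
    merge_height_max = max(x$hclust$height)
  )
}

#' Compartment composition by an annotation attribute
#'
#' Per-cluster percentage breakdown over a categorical annotation (e.g. the
#' peripheral origin, nerve or nerve bundle of the member sensory neurons);
#' each cluster's percentages sum to 100.
#'
#' @param assignment Assignment tibble (`neuron_id`, `cluster`) or a
#'   `compartment_clustering` object.
#' @param annotations Annotation table with `neuron_id` and the chosen
#'   attribute column.
#' @param by Attribute to tally: `"origin"`, `"bundle"` or `"nerve"`.
#' @return Tibble with `cluster`, the attribute, `n` and `percent`.
#' @export
compartment_composition <- function(assignment, annotations,
                                    by = c("origin", "bundle", "nerve")) {
  by <- match.arg(by)
  if (inherits(assignment, "compartment_clustering")) assignment <- assignment$assignment
  assert_cols(assignment, c("neuron_id", "cluster"), "assignment")
  assert_cols(annotations, c("neuron_id", by), "annotations")
  ann <- annotations %>%
    dplyr::transmute(
      neuron_id = as.character(.data$neuron_id),
      value = as.character(.data[[by]])
    )
  joined <- assignment %>%
    dplyr::mutate(neuron_id = as.character(.data$neuron_id)) %>%
    dplyr::left_join(ann, by = "neuron_id")
  missing <- joined$neuron_id[is.na(joined$value)]
  if (length(missing) > 0L) {
    abort(sprintf(
      "missing `%s` annotation for neuron(s): %s",
      by, paste(missing, collapse = ", ")
    ))
  }
  joined %>%
    dplyr::count(.data$cluster, .data$value, name = "n") %>%
    dplyr::group_by(.data$cluster) %>%
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) %>%
    dplyr::ungroup() %>%
    dplyr::rename(!!by := "value") %>%
    dplyr::arrange(.data$cluster, dplyr::desc(.data$n))
}
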
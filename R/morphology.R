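#' Morphology similarity score between two dotprops clouds
#'
#' For every point of the query cloud the nearest point of the target cloud
#' is found; the pair contributes the absolute dot product of their unit
#' tangents, attenuated by a Gaussian of the point distance,
#' `|q_i . t_j| * exp(-d_ij^2 / (2 sigma^2))`. The score is the mean over
#' all query points, lies in \[0, 1\], equals 1 for a self-comparison, and
#' is asymmetric in general. `sigma` sets how close two points must be to
#' count as similar; the reference analysis uses 2 µm.
#'
#' @param query,target [dotprops()] objects.
#' @param sigma Gaussian length scale, nm (default 2000).
#' @return Scalar score in \[0, 1\].
#' @examples
#' q <- dotprops(matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1))
#' t <- dotprops(matrix(c(2000, 0, 0), 1), matrix(c(1, 0, 0), 1))
#' morphology_score(q, t) # exp(-0.5)
#' @export
morphology_score <- function(query, target, sigma = 2000) {
  stopifnot(inherits(query, "dotprops"), inherits(target, "dotprops"))
  assert_scalar_pos(sigma, "sigma")
  nn <- nn_nearest(query$points, target$points)
  # Unit tangents give |q.t| <= 1 up to float residue; snap values within
  # 1e-12 of parallel to exactly 1 so that self-similarity is exactly 1.
  dot <- pmin(abs(rowSums(query$tangents * target$tangents[nn$index, , drop = FALSE])), 1)
  dot[dot >= 1 - 1e-12] <- 1
  mean(dot * exp(-nn$dist^2 / (2 * sigma^2)))
}

#' Pairwise morphology similarity matrix
#'
#' @param dotprops_list A (preferably named) list of [dotprops()] objects;
#'   unnamed lists fall back to each element's `neuron_id`.
#' @param sigma Gaussian length scale, nm.
#' @param symmetrize Replace the asymmetric raw matrix by `(M + t(M)) / 2`
#'   (default `TRUE`; clustering consumes the symmetrized mean).
#' @return Square numeric matrix with unit diagonal and dimnames.
#' @export
morphology_score_matrix <- function(dotprops_list, sigma = 2000, symmetrize = TRUE) {
  if (length(dotprops_list) < 2L) abort("need at least two dotprops to build a matrix")
  labels <- names(dotprops_list) %||%
    vapply(dotprops_list, function(d) as.character(d$neuron_id %||% ""), character(1))
  if (any(labels == "") || anyDuplicated(labels)) {
    labels <- as.character(seq_along(dotprops_list))
  }
  n <- length(dotprops_list)
  m <- matrix(1, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) m[i, j] <- morphology_score(dotprops_list[[i]], dotprops_list[[j]], sigma)
    }
  }
  if (symmetrize) m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}
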
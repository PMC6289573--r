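#' Construct a dotprops object
#'
#' Dotprops represent a neuron as a cloud of 3-D points, each carrying a unit
#' tangent vector describing the local direction of the neurite. Tangent
#' sign is arbitrary (downstream scores use the absolute dot product).
#'
#' @param points n x 3 numeric matrix of positions (nm).
#' @param tangents n x 3 numeric matrix of tangent vectors; normalized to
#'   unit length here.
#' @param k_neighbors Neighbourhood size used when the tangents were fitted
#'   (informational).
#' @param neuron_id Optional source neuron id.
#' @return An object of class `dotprops`.
#' @export
dotprops <- function(points, tangents, k_neighbors = NA_integer_, neuron_id = NULL) {
  points <- as_xyz_matrix(points)
  tangents <- as_xyz_matrix(tangents)
  if (nrow(points) < 1L) abort("dotprops needs at least one point")
  if (!all(dim(points) == dim(tangents))) {
    abort("points and tangents must have matching dimensions")
  }
  if (!all(is.finite(points))) abort("dotprops positions must be finite")
  nrm <- sqrt(rowSums(tangents^2))
  if (any(nrm == 0 | !is.finite(nrm))) abort("tangent vectors must be non-zero and finite")
  structure(
    list(
      points = points,
      tangents = tangents / nrm,
      k_neighbors = k_neighbors,
      neuron_id = neuron_id
    ),
    class = "dotprops"
  )
}

#' @export
print.dotprops <- function(x, ...) {
  cat(sprintf(
    "<dotprops> %d points%s (tangent k = %s)\n",
    nrow(x$points),
    if (is.null(x$neuron_id)) "" else paste0(" from neuron ", x$neuron_id),
    x$k_neighbors
  ))
  invisible(x)
}

#' @export
tidy.dotprops <- function(x, ...) {
  tibble(
    x = x$points[, 1L], y = x$points[, 2L], z = x$points[, 3L],
    tx = x$tangents[, 1L], ty = x$tangents[, 2L], tz = x$tangents[, 3L]
  )
}

#' Convert a skeleton to dotprops
#'
#' The skeleton is decomposed into unbranched segments (root/branch point to
#' branch point/leaf), each segment is resampled at approximately `spacing`
#' intervals along its arc length, and the tangent at every resampled point
#' is the first principal direction of its `k` nearest resampled points.
#'
#' @param skeleton Skeleton tibble (`node_id`, `parent_id`, `x`, `y`, `z`).
#' @param spacing Resampling interval along the neurite, nm (default 1000).
#' @param k Number of nearest points used to fit each tangent (default 5).
#' @param neuron_id Optional id recorded on the result.
#' @return A [dotprops()] object.
#' @export
to_dotprops <- function(skeleton, spacing = 1000, k = 5, neuron_id = NULL) {
  assert_scalar_pos(spacing, "spacing")
  if (k < 2L) abort("`k` must be at least 2")
  rep <- validate_skeleton(skeleton)
  if (!rep$valid) abort("skeleton is not a valid rooted tree; see validate_skeleton()")
  if (nrow(skeleton) < 2L) abort("skeleton has no edge to derive a tangent from")

  pts <- resample_skeleton(skeleton, spacing)
  n <- nrow(pts)
  if (n == 1L) {
    # Degenerate cloud: use the first skeleton edge as the tangent.
    child <- which(!is.na(skeleton$parent_id))[1L]
    parent <- match(skeleton$parent_id[child], skeleton$node_id)
    tangent <- as.numeric(skeleton[child, c("x", "y", "z")]) -
      as.numeric(skeleton[parent, c("x", "y", "z")])
    return(dotprops(pts, matrix(tangent, 1L), k_neighbors = k, neuron_id = neuron_id))
  }

  kk <- min(k, n)
  nn <- RANN::nn2(pts, pts, k = kk)
  tangents <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    nbr <- pts[nn$nn.idx[i, ], , drop = FALSE]
    nbr <- sweep(nbr, 2L, colMeans(nbr))
    tangents[i, ] <- svd(nbr, nu = 0L, nv = 1L)$v[, 1L]
  }
  dotprops(pts, tangents, k_neighbors = k, neuron_id = neuron_id)
}

# Resample a validated skeleton at ~spacing intervals of arc length.
# Segments run between topologically significant nodes (root, branch
# points, leaves); each is sampled at arc positions seq(0, L, spacing).
resample_skeleton <- function(skeleton, spacing) {
  ids <- skeleton$node_id
  idx_of <- stats::setNames(seq_along(ids), ids)
  parent_idx <- ifelse(is.na(skeleton$parent_id), NA_integer_,
    idx_of[as.character(skeleton$parent_id)]
  )
  n_children <- tabulate(parent_idx[!is.na(parent_idx)], nbins = length(ids))
  children <- split(which(!is.na(parent_idx)), parent_idx[!is.na(parent_idx)])
  root <- which(is.na(parent_idx))
  xyz <- as.matrix(skeleton[, c("x", "y", "z")])

  # Segment starts: root and every branch point; follow each child chain
  # until the next branch point or a leaf.
  starts <- unique(c(root, which(n_children > 1L)))
  out <- list()
  for (s in starts) {
    for (first in children[[as.character(s)]] %||% integer(0)) {
      seg <- c(s, first)
      cur <- first
      while (n_children[cur] == 1L) {
        cur <- children[[as.character(cur)]]
        seg <- c(seg, cur)
      }
      p <- xyz[seg, , drop = FALSE]
      step <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
      arc <- c(0, cumsum(step))
      L <- arc[length(arc)]
      at <- seq(0, L, by = spacing)
      if (L == 0) at <- 0
      res <- vapply(
        1:3,
        function(d) stats::approx(arc, p[, d], xout = at, ties = "ordered")$y,
        numeric(length(at))
      )
      out[[length(out) + 1L]] <- matrix(res, ncol = 3L)
    }
  }
  m <- do.call(rbind, out)
  m[!duplicated(m), , drop = FALSE]
}
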
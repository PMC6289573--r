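# Internal helpers shared across modules.

# Nearest neighbour of each query row among the target rows (kd-tree via
# RANN). Distance ties are resolved toward the lowest target row index so
# results are deterministic on degenerate geometry; ties further than the
# `tie_k` nearest neighbours are not detected (irrelevant for non-degenerate
# clouds).
nn_nearest <- function(query, target, tie_k = 8L, tol = 1e-9) {
  query <- as_xyz_matrix(query)
  target <- as_xyz_matrix(target)
  nt <- nrow(target)
  k <- min(nt, tie_k)
  res <- RANN::nn2(target, query, k = k)
  idx <- res$nn.idx[, 1L]
  dist <- res$nn.dists[, 1L]
  if (k > 1L) {
    maybe_tied <- which(res$nn.dists[, 2L] <= dist + tol)
    for (r in maybe_tied) {
      tied <- res$nn.idx[r, res$nn.dists[r, ] <= res$nn.dists[r, 1L] + tol]
      idx[r] <- min(tied)
    }
  }
  list(index = idx, dist = dist)
}

# Count, for every query row, the target rows within Euclidean radius
# (inclusive of the point itself when query == target).
nn_radius_count <- function(query, target, radius) {
  query <- as_xyz_matrix(query)
  target <- as_xyz_matrix(target)
  k <- nrow(target)
  res <- RANN::nn2(target, query, k = k, searchtype = "radius", radius = radius)
  as.integer(rowSums(res$nn.idx > 0L))
}

as_xyz_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.data.frame(x)) {
    return(as.matrix(x[, c("x", "y", "z")]))
  }
  if (is.numeric(x) && length(x) == 3L) {
    return(matrix(as.double(x), nrow = 1L))
  }
  abort("cannot interpret input as 3-D coordinates")
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
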
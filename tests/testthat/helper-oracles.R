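# Independent, loop-based reference implementations ("oracles") used to
# cross-check the package's vectorized / kd-tree / join-based code paths.
# They deliberately avoid RANN, dplyr joins and hclust.

# Nearest target row for each query row; ties -> lowest index.
oracle_nn <- function(query, target) {
  idx <- integer(nrow(query))
  dst <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    d <- sqrt(colSums((t(target) - query[i, ])^2))
    j <- which(d <= min(d) + 0)[1L]
    idx[i] <- j
    dst[i] <- d[j]
  }
  list(index = idx, dist = dst)
}

oracle_morphology_score <- function(q, t, sigma = 2000) {
  total <- 0
  for (i in seq_len(nrow(q$points))) {
    best_d <- Inf
    best_j <- NA_integer_
    for (j in seq_len(nrow(t$points))) {
      d <- sqrt(sum((q$points[i, ] - t$points[j, ])^2))
      if (d < best_d) {
        best_d <- d
        best_j <- j
      }
    }
    dot <- abs(sum(q$tangents[i, ] * t$tangents[best_j, ]))
    total <- total + min(dot, 1) * exp(-best_d^2 / (2 * sigma^2))
  }
  total / nrow(q$points)
}

oracle_local_density <- function(cloud, omega) {
  n <- nrow(cloud)
  out <- integer(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (j in seq_len(n)) {
      if (cloud$polarity[j] != cloud$polarity[i]) next
      d <- sqrt((cloud$x[i] - cloud$x[j])^2 + (cloud$y[i] - cloud$y[j])^2 +
        (cloud$z[i] - cloud$z[j])^2)
      if (d <= omega) cnt <- cnt + 1L
    }
    out[i] <- cnt
  }
  out
}

oracle_synapse_similarity <- function(ci, cj, sigma = 2000, omega = 2000,
                                      unmatched = "zero") {
  ni <- oracle_local_density(ci, omega)
  nj <- oracle_local_density(cj, omega)
  f <- numeric(0)
  for (s in seq_len(nrow(ci))) {
    rows_j <- which(cj$polarity == ci$polarity[s])
    if (length(rows_j) == 0L) {
      if (unmatched == "zero") f <- c(f, 0)
      next
    }
    best_d <- Inf
    best_k <- NA_integer_
    for (k in rows_j) {
      d <- sqrt((ci$x[s] - cj$x[k])^2 + (ci$y[s] - cj$y[k])^2 +
        (ci$z[s] - cj$z[k])^2)
      if (d < best_d) {
        best_d <- d
        best_k <- k
      }
    }
    f <- c(f, exp(-best_d^2 / (2 * sigma^2)) *
      exp(-abs(ni[s] - nj[best_k]) / (ni[s] + nj[best_k])))
  }
  mean(f)
}

# Normalized connectivity similarity re-derived with explicit loops over
# the full node universe.
oracle_connectivity <- function(edges, i, j, c1 = 0.5, c2 = 1) {
  nodes <- sort(unique(c(edges$pre, edges$post)))
  w <- function(a, b) {
    hit <- edges$weight[edges$pre == a & edges$post == b]
    if (length(hit)) sum(hit) else 0
  }
  raw <- 0
  m_max <- 0
  for (k in setdiff(nodes, c(i, j))) {
    for (dir in c("in", "out")) {
      a <- if (dir == "out") w(i, k) else w(k, i)
      b <- if (dir == "out") w(j, k) else w(k, j)
      if (a == 0 && b == 0) next
      raw <- raw + min(a, b) - c1 * max(a, b) * exp(-c2 * min(a, b))
      m_max <- m_max + max(a, b)
    }
  }
  if (m_max == 0) {
    return(NA_real_)
  }
  (raw + c1 * m_max) / ((1 + c1) * m_max)
}

# Naive UPGMA: returns the cophenetic distance matrix implied by greedy
# average-linkage merging of the input distance matrix.
oracle_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  members <- as.list(seq_len(n))
  C <- matrix(0, n, n)
  while (length(members) > 1L) {
    best <- Inf
    ba <- bb <- NA_integer_
    for (a in seq_along(members)) {
      for (b in seq_along(members)) {
        if (a >= b) next
        d <- mean(D[members[[a]], members[[b]]])
        if (d < best) {
          best <- d
          ba <- a
          bb <- b
        }
      }
    }
    C[members[[ba]], members[[bb]]] <- best
    C[members[[bb]], members[[ba]]] <- best
    members[[ba]] <- c(members[[ba]], members[[bb]])
    members[[bb]] <- NULL
  }
  C
}

# Exhaustive DFS path enumeration with the same constraints as
# enumerate_paths: per-edge threshold, simple paths, interneuron-only
# intermediates, 1..max_hops hops.
oracle_paths <- function(edges, annotations, sources, target, threshold = 2,
                         max_hops = 3) {
  g <- edges[edges$weight >= threshold & edges$pre != edges$post, , drop = FALSE]
  cls <- stats::setNames(as.character(annotations$class), as.character(annotations$neuron_id))
  found <- list()
  walk <- function(node, trail, weights) {
    rows <- which(g$pre == node)
    for (r in rows) {
      nxt <- g$post[r]
      w <- g$weight[r]
      if (nxt %in% trail) next
      if (nxt == target) {
        found[[length(found) + 1L]] <<- list(trail = c(trail, nxt), w = c(weights, w))
      } else if (
        length(trail) < max_hops && # room for this edge plus one more
          identical(cls[[nxt]], "interneuron") && !(nxt %in% sources)
      ) {
        walk(nxt, c(trail, nxt), c(weights, w))
      }
    }
  }
  for (s in sources) walk(s, s, numeric(0))
  if (length(found) == 0L) {
    return(tibble::tibble(
      hops = integer(), source = character(), i1 = character(),
      i2 = character(), target = character(),
      w1 = numeric(), w2 = numeric(), w3 = numeric()
    ))
  }
  purrr::map_dfr(found, function(p) {
    h <- length(p$w)
    tibble::tibble(
      hops = h,
      source = p$trail[1L],
      i1 = if (h >= 2L) p$trail[2L] else NA_character_,
      i2 = if (h >= 3L) p$trail[3L] else NA_character_,
      target = target,
      w1 = p$w[1L],
      w2 = if (h >= 2L) p$w[2L] else NA_real_,
      w3 = if (h >= 3L) p$w[3L] else NA_real_
    )
  })
}

# Canonical form of a path table for multiset comparison.
norm_paths <- function(p) {
  out <- as.data.frame(p[, c("hops", "source", "i1", "i2", "target", "w1", "w2", "w3")])
  out$hops <- as.integer(out$hops)
  for (c in c("w1", "w2", "w3")) out[[c]] <- as.numeric(out[[c]])
  out <- out[order(out$hops, out$source, out$i1, out$i2, method = "radix"), ]
  rownames(out) <- NULL
  attributes(out) <- attributes(out)[c("names", "class", "row.names")]
  out
}
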
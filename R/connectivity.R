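#' Single-partner term of the normalized connectivity similarity
#'
#' For the synapse counts `a = A_ik`, `b = A_jk` of two neurons onto a
#' common partner k, the term is
#' `min(a, b) - C1 * max(a, b) * exp(-C2 * min(a, b))`: shared strong
#' connections are rewarded, one-sided connections are punished, and `C1`,
#' `C2` set how severely. Reference values are `C1 = 0.5`, `C2 = 1`.
#'
#' @param a,b Non-negative synapse counts (vectorized).
#' @param c1 Dissimilarity penalty weight in \[0, 1\].
#' @param c2 Decay rate of the penalty with shared synapse count.
#' @return Numeric term(s).
#' @examples
#' conn_pair_term(0, 5) # -2.5
#' conn_pair_term(5, 5) # 5 - 2.5 * exp(-5)
#' @export
conn_pair_term <- function(a, b, c1 = 0.5, c2 = 1) {
  if (any(a < 0) || any(b < 0)) abort("synapse counts must be non-negative")
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  lo - c1 * hi * exp(-c2 * lo)
}

#' Normalized connectivity similarity between two neurons
#'
#' Compares the synaptic partner vectors of neurons i and j over the union
#' of their partners, summing [conn_pair_term()] over every partner and
#' rescaling by the minimal (`-C1 * M`) and maximal (`M`) achievable sums,
#' `M` being the sum of `max(A_ik, A_jk)`, so the score lies in \[0, 1\].
#' Self-connections and the direct i-j connections are excluded; by default
#' incoming and outgoing partner vectors are concatenated (a partner counts
#' separately as an input and as an output). When the two neurons share no
#' partner universe at all (`M = 0`) the score is undefined and `NA` is
#' returned.
#'
#' @param edges Edge list (`pre`, `post`, `weight`) from [build_graph()].
#' @param id_i,id_j Neuron ids to compare (must differ).
#' @param c1,c2 See [conn_pair_term()].
#' @param direction `"both"` (default), `"in"` or `"out"`: which partner
#'   vectors enter the comparison.
#' @return Scalar in \[0, 1\], or `NA` when undefined.
#' @export
connectivity_similarity <- function(edges, id_i, id_j, c1 = 0.5, c2 = 1,
                                    direction = c("both", "in", "out")) {
  direction <- match.arg(direction)
  if (identical(id_i, id_j)) abort("connectivity similarity requires two distinct neurons")
  vi <- partner_vector(edges, id_i, direction, exclude = c(id_i, id_j))
  vj <- partner_vector(edges, id_j, direction, exclude = c(id_i, id_j))
  connectivity_similarity_impl(vi, vj, c1, c2)
}

connectivity_similarity_impl <- function(vi, vj, c1, c2) {
  universe <- union(names(vi), names(vj))
  if (length(universe) == 0L) {
    return(NA_real_)
  }
  a <- ifelse(universe %in% names(vi), vi[universe], 0)
  b <- ifelse(universe %in% names(vj), vj[universe], 0)
  m_max <- sum(pmax(a, b))
  if (m_max == 0) {
    return(NA_real_)
  }
  raw <- sum(conn_pair_term(a, b, c1, c2))
  (raw + c1 * m_max) / ((1 + c1) * m_max)
}

# Directional partner vector of one neuron, partners tagged "in:<id>" /
# "out:<id>" so the same partner counts separately per direction.
partner_vector <- function(edges, id, direction, exclude = id) {
  assert_cols(edges, c("pre", "post", "weight"), "edge list")
  id <- as.character(id)
  exclude <- as.character(exclude)
  out <- edges[edges$pre == id & !(edges$post %in% exclude), ]
  inc <- edges[edges$post == id & !(edges$pre %in% exclude), ]
  v <- c(
    if (direction %in% c("both", "out")) {
      stats::setNames(as.numeric(out$weight), paste0("out:", out$post, recycle0 = TRUE))
    },
    if (direction %in% c("both", "in")) {
      stats::setNames(as.numeric(inc$weight), paste0("in:", inc$pre, recycle0 = TRUE))
    }
  )
  v[v > 0]
}

#' Pairwise normalized connectivity similarity matrix
#'
#' @param edges Edge list from [build_graph()].
#' @param ids Neuron ids to score (default: every node of the graph).
#' @param c1,c2,direction See [connectivity_similarity()].
#' @return Square symmetric matrix with unit diagonal; `NA` marks undefined
#'   pairs (no common partner universe).
#' @export
connectivity_similarity_matrix <- function(edges, ids = NULL, c1 = 0.5, c2 = 1,
                                           direction = c("both", "in", "out")) {
  direction <- match.arg(direction)
  if (is.null(ids)) ids <- sort(unique(c(edges$pre, edges$post)))
  ids <- as.character(ids)
  n <- length(ids)
  if (n < 2L) abort("need at least two neurons to build a matrix")
  m <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      vi <- partner_vector(edges, ids[i], direction, exclude = c(ids[i], ids[j]))
      vj <- partner_vector(edges, ids[j], direction, exclude = c(ids[i], ids[j]))
      s <- connectivity_similarity_impl(vi, vj, c1, c2)
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  m
}
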
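#' Generate random branched skeletons
#'
#' Each skeleton is grown as a biased random walk: the tip advances by
#' `step` nm in a direction mixing the previous direction (`momentum`) with
#' isotropic noise; with probability `branch_prob` the next node instead
#' starts a new branch from a uniformly chosen existing node. Output is
#' deterministic given `seed`.
#'
#' @param n_neurons Number of skeletons.
#' @param n_nodes Nodes per skeleton.
#' @param branch_prob Per-node probability of starting a side branch
#'   (0 gives unbranched chains).
#' @param step Edge length, nm (default 1000).
#' @param momentum Directional persistence in \[0, 1) (default 0.7).
#' @param origin 3-vector, nm: root position of the first neuron;
#'   successive neurons are offset along x by `2 * step * n_nodes`.
#' @param seed Integer RNG seed.
#' @return Named list (`N1`, `N2`, ...) of skeleton tibbles.
#' @export
generate_skeletons <- function(n_neurons = 1, n_nodes = 50, branch_prob = 0.1,
                               step = 1000, momentum = 0.7,
                               origin = c(0, 0, 0), seed = 1) {
  if (n_nodes < 2L) abort("`n_nodes` must be at least 2")
  assert_scalar_pos(step, "step")
  set.seed(seed)
  out <- vector("list", n_neurons)
  for (n in seq_len(n_neurons)) {
    pos <- matrix(0, n_nodes, 3L)
    pos[1L, ] <- origin + c((n - 1L) * 2 * step * n_nodes, 0, 0)
    parent <- rep(NA_integer_, n_nodes)
    dir_of <- matrix(0, n_nodes, 3L)
    dir_of[1L, ] <- rand_unit()
    tip <- 1L
    for (i in 2:n_nodes) {
      if (i > 2L && stats::runif(1) < branch_prob) {
        src <- sample.int(i - 1L, 1L)
        d <- rand_unit()
      } else {
        src <- tip
        d <- momentum * dir_of[src, ] + (1 - momentum) * rand_unit()
        d <- d / sqrt(sum(d^2))
      }
      pos[i, ] <- pos[src, ] + step * d
      dir_of[i, ] <- d
      parent[i] <- src
      tip <- i
    }
    out[[n]] <- tibble(
      node_id = seq_len(n_nodes),
      parent_id = parent,
      x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
      radius = rep(100, n_nodes)
    )
  }
  names(out) <- paste0("N", seq_len(n_neurons))
  out
}

rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) {
      return(v / n)
    }
  }
}

#' Generate a compartmentalized synthetic sensory dataset
#'
#' Emulates the input structure of the compartment analysis: `k` spatially
#' separated convergence zones, each populated by sensory neurons whose
#' presynaptic sites form an isotropic Gaussian cloud around the zone
#' centroid. Centroids sit on a cubic lattice of pitch `separation`, so the
#' minimal pairwise centroid distance equals `separation` (default 20 µm,
#' i.e. 10 x the 2 µm scoring kernel, giving non-overlapping clouds). Sites
#' are emitted as polyadic connectors (the sensory neuron presynaptic, 1-3
#' postsynaptic sites on target interneurons jittered <= 200 nm around the
#' connector).
#'
#' @param k Number of planted compartments (default 7).
#' @param separation Centroid lattice pitch, nm (default 20000).
#' @param spread Per-cloud standard deviation, nm (default 1000).
#' @param neurons_per_cluster Sensory neurons per compartment (default 8).
#' @param synapses_per_neuron Length-2 integer range of presynaptic sites
#'   per neuron (default c(10, 30)).
#' @param n_targets Size of the dummy postsynaptic interneuron pool.
#' @param jitter Maximal postsynaptic-site offset, nm (default 200).
#' @param seed Integer RNG seed.
#' @return List with `connectors`, `annotations`, `labels` (tibble
#'   `neuron_id`, `compartment`: the planted ground truth), `centroids`,
#'   and `params` (including the realized separation/spread ratio).
#' @export
generate_compartment_dataset <- function(k = 7, separation = 20000, spread = 1000,
                                         neurons_per_cluster = 8,
                                         synapses_per_neuron = c(10, 30),
                                         n_targets = 10, jitter = 200, seed = 1) {
  if (k < 1L) abort("`k` must be at least 1")
  assert_scalar_pos(separation, "separation")
  assert_scalar_pos(spread, "spread")
  set.seed(seed)

  grid_n <- ceiling(k^(1 / 3))
  lattice <- as.matrix(expand.grid(
    x = seq_len(max(grid_n, 2L)) - 1L,
    y = seq_len(max(grid_n, 2L)) - 1L,
    z = seq_len(max(grid_n, 2L)) - 1L
  ))[seq_len(k), , drop = FALSE] * separation

  target_pool <- sprintf("I%02d", seq_len(n_targets))
  rows <- list()
  labels <- list()
  cid <- 0L
  for (cl in seq_len(k)) {
    for (nn in seq_len(neurons_per_cluster)) {
      nid <- sprintf("S%02d_%02d", cl, nn)
      labels[[nid]] <- tibble(neuron_id = nid, compartment = cl)
      n_syn <- sample(seq(synapses_per_neuron[1L], synapses_per_neuron[2L]), 1L)
      centre <- lattice[cl, ]
      for (s in seq_len(n_syn)) {
        cid <- cid + 1L
        cpos <- centre + stats::rnorm(3, sd = spread)
        fan <- sample(1:3, 1L)
        posts <- sample(target_pool, fan, replace = FALSE)
        off <- matrix(stats::runif(3 * fan, -1, 1), ncol = 3L)
        off <- off / pmax(sqrt(rowSums(off^2)), 1e-12) * stats::runif(fan, 0, jitter)
        rows[[cid]] <- tibble(
          connector_id = cid,
          pre_neuron = nid,
          post_neuron = posts,
          x = cpos[1L] + off[, 1L],
          y = cpos[2L] + off[, 2L],
          z = cpos[3L] + off[, 3L],
          pre_x = cpos[1L], pre_y = cpos[2L], pre_z = cpos[3L]
        )
      }
    }
  }
  labels <- dplyr::bind_rows(labels)
  connectors <- dplyr::bind_rows(rows)
  origins <- c("enteric", "pharyngeal", "external")
  annotations <- dplyr::bind_rows(
    labels %>% dplyr::transmute(
      neuron_id = .data$neuron_id,
      name = .data$neuron_id,
      class = "sensory",
      nerve = paste0("nerve", (.data$compartment - 1L) %% 3L + 1L),
      bundle = paste0("bundle", .data$compartment),
      origin = origins[(.data$compartment - 1L) %% 3L + 1L],
      side = "left"
    ),
    tibble(
      neuron_id = target_pool, name = target_pool, class = "interneuron",
      nerve = NA_character_, bundle = NA_character_,
      origin = NA_character_, side = "left"
    )
  )
  list(
    connectors = connectors,
    annotations = annotations,
    labels = labels,
    centroids = lattice,
    params = list(
      k = k, separation = separation, spread = spread,
      neurons_per_cluster = neurons_per_cluster,
      synapses_per_neuron = synapses_per_neuron,
      separation_spread_ratio = separation / spread,
      seed = seed
    )
  )
}

#' Generate a layered reflex connectome with planted ground truth
#'
#' Emulates the monosynaptic-reflex-plus-alternative-paths architecture:
#' sensory neurons contact output neurons directly with probability
#' `p_mono`; a layer-2 pool of interneurons receives sensory input and
#' contacts outputs (wiring probability `p_l2`); a layer-3 pool contacts
#' the layer-2 pool (probability `p_l3`) and receives sensory input with
#' probability `p_sens_l3` (so both L3a and L3b interneurons arise). Edge
#' weights are `1 + Geometric(weight_p)` synapses, so a threshold of 2
#' prunes a tunable fraction of edges. Edges are materialized as polyadic
#' connectors (fan-out 1-3), and the ground-truth inventory (L1 edges,
#' per-target L2/L3a/L3b memberships, all valid 1/2/3-hop paths at
#' threshold 2) is computed by direct bookkeeping on the sampled weight
#' matrix, independently of the path-enumeration module.
#'
#' @param n_sensory,n_inter,n_output Population sizes (defaults 30/40/10).
#' @param p_mono Probability of a direct sensory -> output edge (default 0.1).
#' @param p_l2 Wiring probability of the layer-2 pool (default 0.3).
#' @param p_l3 Wiring probability layer-3 pool -> layer-2 pool (default 0.2).
#' @param p_sens_l3 Probability of sensory input onto a layer-3 pool member
#'   (default 0.2).
#' @param weight_p Geometric parameter of the synapse-count distribution
#'   (default 0.5; mean weight 2).
#' @param truth_threshold Synaptic threshold used for the planted inventory
#'   (default 2).
#' @param seed Integer RNG seed.
#' @return List with `connectors`, `annotations`, `edges` (the planted
#'   graph), and `truth`: `l1_edges`, `layers` (per target), `paths` (per
#'   target), all at `truth_threshold`.
#' @export
generate_reflex_connectome <- function(n_sensory = 30, n_inter = 40, n_output = 10,
                                       p_mono = 0.1, p_l2 = 0.3, p_l3 = 0.2,
                                       p_sens_l3 = 0.2, weight_p = 0.5,
                                       truth_threshold = 2, seed = 1) {
  stopifnot(n_sensory >= 1L, n_inter >= 2L, n_output >= 1L)
  for (p in c(p_mono, p_l2, p_l3, p_sens_l3)) {
    if (p < 0 || p > 1) abort("wiring probabilities must lie in [0, 1]")
  }
  set.seed(seed)
  sensory <- sprintf("S%02d", seq_len(n_sensory))
  inter <- sprintf("I%02d", seq_len(n_inter))
  outputs <- sprintf("O%02d", seq_len(n_output))
  pool2 <- inter[seq_len(ceiling(n_inter / 2))]
  pool3 <- setdiff(inter, pool2)

  ids <- c(sensory, inter, outputs)
  W <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  draw <- function(n, p_edge) {
    on <- stats::runif(n) < p_edge
    w <- integer(n)
    w[on] <- 1L + stats::rgeom(sum(on), weight_p)
    w
  }
  W[sensory, outputs] <- draw(n_sensory * n_output, p_mono)
  W[sensory, pool2] <- draw(n_sensory * length(pool2), p_l2)
  W[pool2, outputs] <- draw(length(pool2) * n_output, p_l2)
  if (length(pool3) > 0L) {
    W[pool3, pool2] <- draw(length(pool3) * length(pool2), p_l3)
    W[sensory, pool3] <- draw(n_sensory * length(pool3), p_sens_l3)
  }

  connectors <- weights_to_connectors(W)
  annotations <- tibble(
    neuron_id = ids,
    name = ids,
    class = c(
      rep("sensory", n_sensory), rep("interneuron", n_inter),
      rep(c("neurosecretory", "motor"), length.out = n_output)
    ),
    nerve = "AN", bundle = NA_character_, origin = NA_character_,
    side = "left",
    compartment = c(
      paste0("C", (seq_len(n_sensory) - 1L) %% 3L + 1L),
      rep(NA_character_, n_inter + n_output)
    )
  )

  truth <- reflex_truth(W, sensory, inter, outputs, truth_threshold)
  nz <- which(W > 0L, arr.ind = TRUE)
  edges <- tibble(
    pre = ids[nz[, 1L]], post = ids[nz[, 2L]], weight = as.integer(W[nz])
  ) %>% dplyr::arrange(.data$pre, .data$post)
  list(
    connectors = connectors,
    annotations = annotations,
    edges = edges,
    truth = truth,
    params = list(
      n_sensory = n_sensory, n_inter = n_inter, n_output = n_output,
      p_mono = p_mono, p_l2 = p_l2, p_l3 = p_l3, p_sens_l3 = p_sens_l3,
      weight_p = weight_p, truth_threshold = truth_threshold, seed = seed
    )
  )
}

# Materialize a weight matrix as polyadic connectors: each presynaptic
# neuron's unit connections are chunked into connectors of fan-out 1-3; a
# connector never contacts the same postsynaptic neuron twice. Connector
# positions are uniform in a 50 um box; postsynaptic sites jitter <= 200 nm.
weights_to_connectors <- function(W) {
  ids <- rownames(W)
  rows <- list()
  cid <- 0L
  for (pre in ids) {
    w <- W[pre, ]
    units <- rep(names(w), times = w)
    while (length(units) > 0L) {
      cid <- cid + 1L
      fan <- min(sample(1:3, 1L), length(units))
      take <- integer(0)
      seen <- character(0)
      for (u in seq_along(units)) {
        if (!(units[u] %in% seen)) {
          take <- c(take, u)
          seen <- c(seen, units[u])
          if (length(take) == fan) break
        }
      }
      posts <- units[take]
      units <- units[-take]
      cpos <- stats::runif(3, 0, 50000)
      off <- matrix(stats::runif(3 * length(posts), -200, 200), ncol = 3L)
      rows[[cid]] <- tibble(
        connector_id = cid,
        pre_neuron = pre,
        post_neuron = posts,
        x = cpos[1L] + off[, 1L],
        y = cpos[2L] + off[, 2L],
        z = cpos[3L] + off[, 3L],
        pre_x = cpos[1L], pre_y = cpos[2L], pre_z = cpos[3L]
      )
    }
  }
  if (cid == 0L) {
    return(tibble(
      connector_id = integer(), pre_neuron = character(),
      post_neuron = character(), x = double(), y = double(), z = double(),
      pre_x = double(), pre_y = double(), pre_z = double()
    ))
  }
  dplyr::bind_rows(rows)
}

# Planted ground truth by direct index bookkeeping on the weight matrix
# (independent of the dplyr-join path enumeration it validates).
reflex_truth <- function(W, sensory, inter, outputs, t) {
  A <- W >= t
  l1 <- which(A[sensory, outputs, drop = FALSE], arr.ind = TRUE)
  l1_edges <- tibble(
    source = sensory[l1[, 1L]], target = outputs[l1[, 2L]],
    weight = W[sensory, outputs, drop = FALSE][l1]
  ) %>% dplyr::arrange(.data$source, .data$target)

  layers <- list()
  paths <- list()
  for (o in outputs) {
    u1 <- inter[A[inter, o]]
    l2 <- u1[vapply(u1, function(i) any(A[sensory, i]), logical(1))]
    l3 <- character(0)
    for (j in inter) {
      if (!(j %in% u1) && any(A[j, u1])) l3 <- c(l3, j)
    }
    l3a <- l3[vapply(l3, function(j) any(A[sensory, j]), logical(1))]
    l3b <- setdiff(l3, l3a)
    l1s <- sensory[A[sensory, o]]
    layers[[o]] <- dplyr::bind_rows(
      tibble(neuron_id = l1s, layer = "L1-source"),
      tibble(neuron_id = l2, layer = "L2"),
      tibble(neuron_id = l3a, layer = "L3a"),
      tibble(neuron_id = l3b, layer = "L3b"),
      tibble(neuron_id = o, layer = "output")
    ) %>% dplyr::mutate(target = o)

    p <- list()
    for (s in sensory) {
      if (A[s, o]) {
        p[[length(p) + 1L]] <- tibble(
          hops = 1L, source = s, i1 = NA_character_, i2 = NA_character_,
          target = o, w1 = W[s, o], w2 = NA_integer_, w3 = NA_integer_
        )
      }
      for (i1 in inter[A[s, inter]]) {
        if (A[i1, o]) {
          p[[length(p) + 1L]] <- tibble(
            hops = 2L, source = s, i1 = i1, i2 = NA_character_,
            target = o, w1 = W[s, i1], w2 = W[i1, o], w3 = NA_integer_
          )
        }
        for (i2 in inter[A[i1, inter]]) {
          if (i2 != i1 && A[i2, o]) {
            p[[length(p) + 1L]] <- tibble(
              hops = 3L, source = s, i1 = i1, i2 = i2,
              target = o, w1 = W[s, i1], w2 = W[i1, i2], w3 = W[i2, o]
            )
          }
        }
      }
    }
    paths[[o]] <- if (length(p) > 0L) dplyr::bind_rows(p) else NULL
  }
  list(
    l1_edges = l1_edges,
    layers = dplyr::bind_rows(layers),
    paths = dplyr::bind_rows(paths) %>%
      dplyr::arrange(.data$target, .data$hops, .data$source, .data$i1, .data$i2),
    threshold = t
  )
}
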
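test_that("percent of synaptic connections partitions to 100", {
  e <- tibble::tibble(pre = c("A", "A"), post = c("B", "C"), weight = c(3L, 1L))
  expect_equal(percent_synaptic_connections(e, "A", "B", "outgoing"), 75)
  expect_equal(percent_synaptic_connections(e, "A", c("B", "C"), "outgoing"), 100)
  expect_warning(
    out <- percent_synaptic_connections(e, "A", "B", "incoming"),
    "undefined"
  )
  expect_true(is.na(out))

  g <- rand_graph(20, seed = 13)
  nodes <- unique(c(g$edges$pre, g$edges$post))
  n <- nodes[which.max(vapply(nodes, function(x) sum(g$edges$weight[g$edges$pre == x]), numeric(1)))]
  partners <- unique(g$edges$post[g$edges$pre == n])
  blocks <- split(partners, rep(1:3, length.out = length(partners)))
  pct <- vapply(
    blocks,
    function(b) percent_synaptic_connections(g$edges, n, b, "outgoing"),
    numeric(1)
  )
  expect_equal(sum(pct), 100)
})

test_that("ranking index is the synapse count over the strongest input", {
  e <- tibble::tibble(pre = c("X", "A"), post = "B", weight = c(10L, 5L))
  expect_equal(ranking_index(e, "A", "B"), 0.5)
  expect_equal(ranking_index(e, "X", "B"), 1)
  expect_error(ranking_index(e, "A", "Z"), "no incoming")
  expect_error(ranking_index(e, "Q", "B"), "no connection")

  g <- rand_graph(25, seed = 17)
  tgts <- unique(g$edges$post)
  for (tgt in utils::head(tgts, 5)) {
    inc <- g$edges[g$edges$post == tgt, ]
    top <- inc$pre[which.max(inc$weight)]
    expect_equal(ranking_index(g$edges, top, tgt), 1)
    for (src in inc$pre) {
      expect_equal(
        ranking_index(g$edges, src, tgt),
        inc$weight[inc$pre == src] / max(inc$weight)
      )
      expect_lte(ranking_index(g$edges, src, tgt), 1)
    }
  }
})

test_that("thresholding removes exactly the sub-threshold edges", {
  e <- tibble::tibble(pre = c("A", "B", "C"), post = "D", weight = c(1L, 2L, 3L))
  expect_equal(threshold_graph(e, 2)$weight, c(2L, 3L))
  expect_identical(threshold_graph(e, 1), e)
  g <- rand_graph(30, seed = 23)
  for (t in 1:4) {
    expect_equal(
      nrow(threshold_graph(g$edges, t)),
      sum(g$edges$weight >= t)
    )
  }
})

test_that("path enumeration handles the elementary circuits", {
  ps <- chain_path_set()
  p <- tidy(ps)
  expect_equal(nrow(p), 1L)
  expect_equal(p$hops, 2L)
  expect_equal(p$i1, "I1")

  # sub-threshold middle edge kills the path
  edges <- tibble::tibble(pre = c("S1", "I1"), post = c("I1", "O1"), weight = c(3L, 1L))
  ann <- tibble::tibble(
    neuron_id = c("S1", "I1", "O1"),
    class = c("sensory", "interneuron", "motor")
  )
  expect_equal(nrow(tidy(enumerate_paths(edges, ann, "S1", "O1", threshold = 2))), 0L)

  expect_error(enumerate_paths(edges, ann, c("S1", "O1"), "O1"), "sources")
})

test_that("path enumeration matches the exhaustive DFS oracle", {
  for (seed in 1:30) {
    g <- rand_graph(n_nodes = sample(10:40, 1), p_edge = 0.1, seed = seed)
    if (length(g$sensory) == 0 || length(g$motor) == 0) next
    tgt <- g$motor[1]
    ps <- enumerate_paths(g$edges, g$annotations, g$sensory, tgt, threshold = 2)
    want <- oracle_paths(g$edges, g$annotations, g$sensory, tgt, threshold = 2)
    expect_equal(norm_paths(tidy(ps)), norm_paths(want))
  }
})

test_that("raising the threshold never adds a path", {
  for (seed in c(2, 9)) {
    g <- rand_graph(30, p_edge = 0.12, seed = seed)
    if (length(g$sensory) == 0 || length(g$motor) == 0) next
    tgt <- g$motor[1]
    counts <- vapply(1:4, function(t) {
      nrow(tidy(enumerate_paths(g$edges, g$annotations, g$sensory, tgt, threshold = t)))
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
    # and each higher-threshold path set is a subset
    lo <- norm_paths(tidy(enumerate_paths(g$edges, g$annotations, g$sensory, tgt, threshold = 2)))
    hi <- norm_paths(tidy(enumerate_paths(g$edges, g$annotations, g$sensory, tgt, threshold = 3)))
    expect_equal(nrow(dplyr::anti_join(hi, lo, by = names(hi))), 0L)
  }
})

test_that("the 3-hop direct-upstream restriction flag is a superset check", {
  for (seed in c(5, 21)) {
    g <- rand_graph(30, p_edge = 0.12, seed = seed)
    if (length(g$sensory) == 0 || length(g$motor) == 0) next
    tgt <- g$motor[1]
    restr <- norm_paths(tidy(enumerate_paths(
      g$edges, g$annotations, g$sensory, tgt,
      threshold = 2, restrict_3hop = TRUE
    )))
    unrestr <- norm_paths(tidy(enumerate_paths(
      g$edges, g$annotations, g$sensory, tgt,
      threshold = 2, restrict_3hop = FALSE
    )))
    expect_equal(nrow(dplyr::anti_join(restr, unrestr, by = names(restr))), 0L)
  }
})

test_that("layer assignment follows the backward-traversal definitions", {
  # S -> I -> O only: I is L2
  edges <- tibble::tibble(pre = c("S1", "I1"), post = c("I1", "O1"), weight = c(2L, 2L))
  ann <- tibble::tibble(
    neuron_id = c("S1", "I1", "O1"),
    class = c("sensory", "interneuron", "motor")
  )
  ly <- assign_layers(edges, ann, "S1", "O1")
  expect_equal(ly$layer[ly$neuron_id == "I1"], "L2")

  # J feeds the direct upstream but receives no sensory input: L3b
  edges <- tibble::tibble(
    pre = c("S1", "I1", "J1"), post = c("I1", "O1", "I1"), weight = 2L
  )
  ann <- tibble::tibble(
    neuron_id = c("S1", "I1", "J1", "O1"),
    class = c("sensory", "interneuron", "interneuron", "motor")
  )
  ly <- assign_layers(edges, ann, "S1", "O1")
  expect_equal(ly$layer[ly$neuron_id == "J1"], "L3b")

  # give J1 a strong sensory input: becomes L3a
  edges2 <- dplyr::bind_rows(edges, tibble::tibble(pre = "S1", post = "J1", weight = 2L))
  ly2 <- assign_layers(edges2, ann, "S1", "O1")
  expect_equal(ly2$layer[ly2$neuron_id == "J1"], "L3a")

  # random fixture: partition equals an independent set-algebra oracle
  for (seed in c(3, 14)) {
    g <- rand_graph(30, p_edge = 0.12, seed = seed)
    if (length(g$sensory) == 0 || length(g$motor) == 0) next
    tgt <- g$motor[1]
    ly <- assign_layers(g$edges, g$annotations, g$sensory, tgt, threshold = 2)
    gt <- g$edges[g$edges$weight >= 2 & g$edges$pre != g$edges$post, ]
    inter <- setdiff(
      g$annotations$neuron_id[g$annotations$class == "interneuron"],
      c(g$sensory, tgt)
    )
    u1 <- unique(gt$pre[gt$post == tgt & gt$pre %in% inter])
    sens_in <- function(n) any(gt$pre %in% g$sensory & gt$post == n)
    l2 <- sort(u1[vapply(u1, sens_in, logical(1))])
    l3 <- sort(setdiff(unique(gt$pre[gt$post %in% u1 & gt$pre %in% inter]), c(u1, tgt)))
    l3a <- l3[vapply(l3, sens_in, logical(1))]
    expect_setequal(ly$neuron_id[ly$layer == "L2"], l2)
    expect_setequal(ly$neuron_id[ly$layer == "L3a"], l3a)
    expect_setequal(ly$neuron_id[ly$layer == "L3b"], setdiff(l3, l3a))
    # L3a and L3b disjoint; L2 members all appear on a 2-hop path
    expect_length(intersect(
      ly$neuron_id[ly$layer == "L3a"],
      ly$neuron_id[ly$layer == "L3b"]
    ), 0)
    p2 <- tidy(enumerate_paths(g$edges, g$annotations, g$sensory, tgt, threshold = 2))
    expect_true(all(ly$neuron_id[ly$layer == "L2"] %in% p2$i1[p2$hops == 2]))
  }
})

test_that("convergence and divergence tally distinct routes", {
  edges <- tibble::tibble(
    pre = c("S1", "S2", "I1", "S3", "I2", "I3", "S3", "S3"),
    post = c("I1", "I1", "O1", "I2", "O1", "O1", "I3", "I2"),
    weight = 2L
  )
  edges <- dplyr::bind_rows(edges, tibble::tibble(pre = "S3", post = "I3", weight = 2L)) |>
    dplyr::distinct()
  ann <- tibble::tibble(
    neuron_id = c("S1", "S2", "S3", "I1", "I2", "I3", "O1"),
    class = c(rep("sensory", 3), rep("interneuron", 3), "motor")
  )
  ps <- enumerate_paths(edges, ann, c("S1", "S2", "S3"), "O1", threshold = 2)
  cd <- convergence_divergence(ps)
  expect_equal(cd$convergence$degree[cd$convergence$interneuron == "I1"], 2L)
  expect_equal(cd$divergence$divergence[cd$divergence$source == "S3"], 2L)

  # tally oracle on a random path set
  g <- rand_graph(30, p_edge = 0.12, seed = 31)
  tgt <- g$motor[1]
  ps <- enumerate_paths(g$edges, g$annotations, g$sensory, tgt, threshold = 2)
  cd <- convergence_divergence(ps)
  p2 <- tidy(ps)[tidy(ps)$hops == 2, ]
  expect_equal(
    sum(cd$convergence$degree),
    nrow(unique(p2[, c("source", "i1")]))
  )
  for (r in seq_len(nrow(cd$divergence))) {
    expect_equal(
      cd$divergence$divergence[r],
      length(unique(p2$i1[p2$source == cd$divergence$source[r]]))
    )
  }
})

test_that("common interneurons require threshold contacts on both legs", {
  edges <- tibble::tibble(
    pre = c("M1", "I1", "M2", "I2", "S1"),
    post = c("I1", "O1", "I2", "O1", "I1"),
    weight = c(2L, 2L, 1L, 2L, 2L)
  )
  ann <- tibble::tibble(
    neuron_id = c("M1", "M2", "I1", "I2", "O1", "S1"),
    class = c("MBON", "MBON", "interneuron", "interneuron", "neurosecretory", "sensory")
  )
  ci <- common_interneurons(edges, ann,
    upstream_set = c("M1", "M2"),
    output_set = "O1", sensory = "S1", threshold = 2
  )
  expect_equal(ci$interneuron, "I1") # I2 fails the M -> I leg at t = 2
  expect_equal(ci$layer, "L2")
  expect_error(
    common_interneurons(edges, ann, c("M1", "O1"), "O1", "S1"),
    "disjoint"
  )

  # double-filter oracle on a random fixture
  g <- rand_graph(35, p_edge = 0.12, seed = 41)
  mb <- g$annotations$neuron_id[g$annotations$class == "motor"][1:2]
  outs <- setdiff(g$annotations$neuron_id[g$annotations$class == "motor"], mb)
  if (length(outs) > 0) {
    ci <- common_interneurons(g$edges, g$annotations, mb, outs, g$sensory, threshold = 2)
    gt <- g$edges[g$edges$weight >= 2, ]
    inter <- g$annotations$neuron_id[g$annotations$class == "interneuron"]
    want <- expand.grid(
      interneuron = inter, output = outs,
      stringsAsFactors = FALSE
    )
    keep <- vapply(seq_len(nrow(want)), function(r) {
      any(gt$pre %in% mb & gt$post == want$interneuron[r]) &&
        any(gt$pre == want$interneuron[r] & gt$post == want$output[r])
    }, logical(1))
    want <- want[keep, ]
    expect_equal(
      as.data.frame(ci[, c("interneuron", "output")]),
      want[order(want$interneuron, want$output), ],
      ignore_attr = TRUE
    )
  }
})

test_that("fraction of connected compartment members matches a member scan", {
  assignment <- tibble::tibble(
    neuron_id = sprintf("S%d", 1:10),
    cluster = rep(1:2, each = 5)
  )
  edges <- tibble::tibble(
    pre = sprintf("S%d", 1:9), post = "O1", weight = c(rep(2L, 9))
  )
  frac <- fraction_neurons_connected(
    assignment, edges,
    relation = "monosynaptic-to-outputs", output_set = "O1"
  )
  expect_equal(frac$percent[frac$cluster == 1], 100)
  expect_equal(frac$percent[frac$cluster == 2], 80)

  # threshold above all weights -> 0 everywhere
  frac0 <- fraction_neurons_connected(
    assignment, edges,
    relation = "monosynaptic-to-outputs", threshold = 5, output_set = "O1"
  )
  expect_true(all(frac0$percent == 0))

  # intra-compartment sensory relation, either direction counts
  edges2 <- tibble::tibble(pre = "S1", post = "S2", weight = 2L)
  fr <- fraction_neurons_connected(assignment, edges2,
    relation = "intra-compartment-sensory"
  )
  expect_equal(fr$percent[fr$cluster == 1], 40) # S1 and S2 of 5
  expect_equal(fr$percent[fr$cluster == 2], 0)

  # member-scan oracle on a random fixture
  g <- rand_graph(30, p_edge = 0.15, seed = 51)
  sens <- g$sensory
  if (length(sens) >= 4) {
    assignment <- tibble::tibble(
      neuron_id = sens,
      cluster = rep(1:2, length.out = length(sens))
    )
    fr <- fraction_neurons_connected(assignment, g$edges,
      relation = "intra-compartment-sensory", threshold = 2
    )
    gt <- g$edges[g$edges$weight >= 2 & g$edges$pre != g$edges$post, ]
    for (cl in 1:2) {
      members <- assignment$neuron_id[assignment$cluster == cl]
      hits <- sum(vapply(members, function(m) {
        any((gt$pre == m & gt$post %in% setdiff(members, m)) |
          (gt$post == m & gt$pre %in% setdiff(members, m)))
      }, logical(1)))
      expect_equal(fr$n_connected[fr$cluster == cl], hits)
    }
  }
})
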
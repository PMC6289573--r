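test_that("skeleton generation is deterministic and honours its knobs", {
  a <- generate_skeletons(n_neurons = 3, n_nodes = 40, seed = 5)
  b <- generate_skeletons(n_neurons = 3, n_nodes = 40, seed = 5)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_swc(a[[2]], f1)
  write_swc(b[[2]], f2)
  expect_identical(readLines(f1), readLines(f2))

  chains <- generate_skeletons(n_neurons = 2, n_nodes = 25, branch_prob = 0, seed = 1)
  for (sk in chains) {
    expect_equal(nrow(sk), 25L)
    expect_true(validate_skeleton(sk)$valid)
    # unbranched: every node except the leaf has exactly one child
    kids <- table(sk$parent_id)
    expect_true(all(kids == 1))
  }

  branched <- generate_skeletons(n_neurons = 1, n_nodes = 60, branch_prob = 0.3, seed = 3)[[1]]
  expect_true(validate_skeleton(branched)$valid)
  expect_true(any(table(branched$parent_id) > 1))
})

test_that("compartment datasets satisfy the connector-table invariants", {
  d <- generate_compartment_dataset(k = 3, neurons_per_cluster = 3, seed = 8)
  g <- build_graph(d$connectors)
  expect_identical(sum(g$weight), nrow(d$connectors))
  expect_equal(nrow(d$labels), 9L)
  expect_true(all(d$connectors$pre_neuron %in% d$labels$neuron_id))
  # post-site jitter stays within 200 nm of the connector
  delta <- sqrt((d$connectors$x - d$connectors$pre_x)^2 +
    (d$connectors$y - d$connectors$pre_y)^2 +
    (d$connectors$z - d$connectors$pre_z)^2)
  expect_lte(max(delta), 200)
  # same seed -> identical tables
  d2 <- generate_compartment_dataset(k = 3, neurons_per_cluster = 3, seed = 8)
  expect_identical(as.data.frame(d$connectors), as.data.frame(d2$connectors))
  # min centroid separation equals the requested pitch
  cd <- as.matrix(stats::dist(d$centroids))
  expect_equal(min(cd[cd > 0]), d$params$separation)
})

test_that("a single planted compartment yields uniformly high similarity", {
  d <- generate_compartment_dataset(k = 1, neurons_per_cluster = 6, seed = 15)
  cl <- synapse_clouds(d$connectors)
  s <- synapse_similarity_matrix(
    cl[cl$neuron_id %in% d$labels$neuron_id, ],
    ids = sort(d$labels$neuron_id)
  )
  expect_gt(min(s), 0.5)
})

test_that("at enormous spread the planted structure dissolves", {
  d <- generate_compartment_dataset(
    k = 2, neurons_per_cluster = 5,
    spread = 1e9, seed = 77
  )
  cl <- synapse_clouds(d$connectors)
  s <- synapse_similarity_matrix(
    cl[cl$neuron_id %in% d$labels$neuron_id, ],
    ids = sort(d$labels$neuron_id)
  )
  lab <- d$labels$compartment[match(rownames(s), d$labels$neuron_id)]
  same <- outer(lab, lab, "==") & upper.tri(s)
  diff <- (!outer(lab, lab, "==")) & upper.tri(s)
  ks <- stats::ks.test(s[same], s[diff])
  expect_gt(ks$p.value, 0.01)
})

test_that("reflex connectome generation plants what it reports", {
  r <- generate_reflex_connectome(
    n_sensory = 12, n_inter = 10, n_output = 3,
    seed = 4
  )
  g <- build_graph(r$connectors)
  expect_identical(
    as.data.frame(g),
    as.data.frame(r$edges)
  )
  expect_identical(sum(g$weight), nrow(r$connectors))
  # connectors never contact the same postsynaptic neuron twice
  dup <- r$connectors |>
    dplyr::count(connector_id, post_neuron) |>
    dplyr::filter(n > 1)
  expect_equal(nrow(dup), 0L)

  # degenerate wiring: no interneuron layers at all
  r0 <- generate_reflex_connectome(
    n_sensory = 8, n_inter = 4, n_output = 2,
    p_l2 = 0, p_l3 = 0, p_sens_l3 = 0, seed = 6
  )
  expect_true(all(r0$truth$paths$hops == 1))
  expect_false(any(r0$truth$layers$layer %in% c("L2", "L3a", "L3b")))
  g0 <- build_graph(r0$connectors)
  ann0 <- r0$annotations
  ly <- assign_layers(
    g0, ann0, ann0$neuron_id[ann0$class == "sensory"],
    "O01",
    threshold = 2
  )
  expect_false(any(ly$layer %in% c("L2", "L3a", "L3b")))

  # no monosynaptic edges -> zero monosynaptic fraction everywhere
  rm0 <- generate_reflex_connectome(
    n_sensory = 8, n_inter = 6, n_output = 2,
    p_mono = 0, seed = 9
  )
  gm <- build_graph(rm0$connectors)
  annm <- rm0$annotations
  sens <- annm$neuron_id[annm$class == "sensory"]
  frac <- fraction_neurons_connected(
    tibble::tibble(neuron_id = sens, cluster = annm$compartment[match(sens, annm$neuron_id)]),
    gm,
    relation = "monosynaptic-to-outputs",
    output_set = annm$neuron_id[annm$class %in% c("motor", "neurosecretory")]
  )
  expect_true(all(frac$percent == 0))
  expect_equal(nrow(rm0$truth$l1_edges), 0L)
})

test_that("circuit-path recovery matches the planted inventory", {
  for (seed in 1:5) {
    r <- generate_reflex_connectome(
      n_sensory = 12, n_inter = 12, n_output = 3,
      seed = seed
    )
    g <- build_graph(r$connectors)
    ann <- r$annotations
    sens <- ann$neuron_id[ann$class == "sensory"]
    outs <- ann$neuron_id[ann$class %in% c("motor", "neurosecretory")]
    for (o in outs) {
      ps <- enumerate_paths(g, ann, sens, o, threshold = 2)
      want <- r$truth$paths[r$truth$paths$target == o, ]
      expect_equal(norm_paths(tidy(ps)), norm_paths(want))
      ly <- assign_layers(g, ann, sens, o, threshold = 2)
      want_ly <- r$truth$layers[r$truth$layers$target == o, c("neuron_id", "layer")]
      expect_equal(
        as.data.frame(dplyr::arrange(ly, layer, neuron_id)),
        as.data.frame(dplyr::arrange(want_ly, layer, neuron_id))
      )
    }
  }
})
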
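test_that("local density counts same-polarity sites within omega, self inclusive", {
  lone <- tibble::tibble(x = 0, y = 0, z = 0, polarity = "pre")
  expect_equal(local_density(lone, 2000), 1L)

  cl <- tibble::tibble(
    x = c(0, 500, 1000, 9000), y = 0, z = 0,
    polarity = rep("pre", 4)
  )
  expect_equal(local_density(cl, 2000), c(3L, 3L, 3L, 1L))

  mixed <- tibble::tibble(
    x = c(0, 10, 20), y = 0, z = 0,
    polarity = c("pre", "post", "post")
  )
  expect_equal(local_density(mixed, 2000), c(1L, 2L, 2L))

  set.seed(2)
  cl <- rand_cloud(40, seed = 2)
  expect_equal(local_density(cl, 1500), oracle_local_density(cl, 1500))
})

test_that("synapse similarity reproduces its closed forms", {
  ci <- tibble::tibble(x = 0, y = 0, z = 0, polarity = "pre")
  cj <- tibble::tibble(x = 2000, y = 0, z = 0, polarity = "pre")
  expect_equal(synapse_similarity(ci, cj), exp(-0.5), tolerance = 1e-14)
  expect_identical(synapse_similarity(ci, ci), 1)

  # co-located but 3 vs 1 sites within omega: exp(0) * exp(-2/4)
  ci3 <- tibble::tibble(x = c(0, 0, 0), y = 0, z = 0, polarity = "pre")
  expect_equal(synapse_similarity(ci3, ci), exp(-0.5), tolerance = 1e-14)

  # density factor bound: co-located sites never drop below exp(-1)
  ci9 <- tibble::tibble(x = rep(0, 9), y = 0, z = 0, polarity = "pre")
  expect_gte(synapse_similarity(ci9, ci), exp(-1))
})

test_that("polarity is respected: opposite-sign sites never match", {
  ci <- tibble::tibble(x = 0, y = 0, z = 0, polarity = "pre")
  cj_post <- tibble::tibble(x = 0, y = 0, z = 0, polarity = "post")
  expect_error(synapse_similarity(ci, cj_post), "polarity")

  both <- tibble::tibble(
    x = c(0, 0), y = 0, z = 0, polarity = c("pre", "post")
  )
  # moving the opposite-polarity site far away leaves the score unchanged
  moved <- tibble::tibble(
    x = c(0, 99999), y = 0, z = 0, polarity = c("pre", "post")
  )
  ci_pre <- tibble::tibble(x = 100, y = 0, z = 0, polarity = "pre")
  expect_equal(
    synapse_similarity(ci_pre, both),
    synapse_similarity(ci_pre, moved)
  )

  # unmatched sites contribute 0 by default, or can be skipped
  ci_mixed <- tibble::tibble(
    x = c(0, 0), y = 0, z = 0, polarity = c("pre", "post")
  )
  cj_pre <- tibble::tibble(x = 0, y = 0, z = 0, polarity = "pre")
  s_zero <- synapse_similarity(ci_mixed, cj_pre, unmatched = "zero")
  s_skip <- synapse_similarity(ci_mixed, cj_pre, unmatched = "skip")
  expect_equal(s_zero, s_skip / 2)
})

test_that("score is bounded, self-identical and decays under translation", {
  for (seed in 1:5) {
    ci <- rand_cloud(20, seed = seed)
    expect_identical(synapse_similarity(ci, ci), 1)
    cj <- rand_cloud(15, seed = seed + 30)
    s <- synapse_similarity(ci, cj)
    expect_gte(s, 0)
    expect_lte(s, 1)
  }

  ci <- rand_cloud(25, seed = 7, polarities = "pre")
  shifts <- c(0, 1000, 2000, 4000, 8000, 20000)
  scores <- vapply(shifts, function(delta) {
    cj <- dplyr::mutate(ci, x = x + delta)
    synapse_similarity(ci, cj)
  }, numeric(1))
  expect_true(all(diff(scores) <= 1e-12))

  # separation of 10 sigma extinguishes similarity
  far <- dplyr::mutate(ci, x = x + 10 * 2000 + max(ci$x))
  expect_lt(synapse_similarity(ci, far), 1e-10)
})

test_that("kd-tree scoring matches the brute-force oracle", {
  for (seed in 1:5) {
    ci <- rand_cloud(30, seed = seed)
    cj <- rand_cloud(25, seed = seed + 60)
    expect_equal(
      synapse_similarity(ci, cj),
      oracle_synapse_similarity(ci, cj),
      tolerance = 1e-12
    )
  }
})

test_that("similarity matrix equals the per-pair computation", {
  set.seed(31)
  clouds <- tibble::tibble(
    neuron_id = rep(sprintf("n%d", 1:6), each = 12),
    x = stats::runif(72, 0, 8000),
    y = stats::runif(72, 0, 8000),
    z = stats::runif(72, 0, 8000),
    polarity = sample(c("pre", "post"), 72, replace = TRUE)
  )
  m <- synapse_similarity_matrix(clouds, symmetrize = FALSE)
  by_id <- split(clouds[, c("x", "y", "z", "polarity")], clouds$neuron_id)
  for (i in names(by_id)) {
    for (j in names(by_id)) {
      if (i != j) {
        expect_equal(
          m[i, j],
          oracle_synapse_similarity(by_id[[i]], by_id[[j]]),
          tolerance = 1e-12
        )
      }
    }
  }
  expect_equal(unname(diag(m)), rep(1, 6))

  twin <- synapse_similarity_matrix(
    dplyr::bind_rows(
      dplyr::mutate(by_id[["n1"]], neuron_id = "a"),
      dplyr::mutate(by_id[["n1"]], neuron_id = "b")
    )
  )
  expect_equal(unname(twin["a", "b"]), 1)
})

test_that("synapse_clouds splits connectors into polarity-tagged sites", {
  con <- tibble::tibble(
    connector_id = c(1, 1, 2),
    pre_neuron = c("A", "A", "B"),
    post_neuron = c("B", "C", "A"),
    x = c(10, 20, 100), y = 0, z = 0,
    pre_x = c(0, 0, 105), pre_y = 0, pre_z = 0
  )
  cl <- synapse_clouds(con)
  a <- cl[cl$neuron_id == "A", ]
  # A: one pre site (connector 1) + one post site (connector 2)
  expect_equal(sort(a$polarity), c("post", "pre"))
  expect_equal(a$x[a$polarity == "pre"], 0)
  expect_equal(a$x[a$polarity == "post"], 100)
  # without pre positions, the connector centroid is used
  cl2 <- synapse_clouds(con[, 1:6])
  expect_equal(cl2$x[cl2$neuron_id == "A" & cl2$polarity == "pre"], 15)
})
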
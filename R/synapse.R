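#' Extract per-neuron synapse clouds from a connector table
#'
#' Every neuron's synaptic sites, tagged by polarity: one presynaptic site
#' per connector for its presynaptic neuron (at the `pre_x/pre_y/pre_z`
#' position when present, otherwise at the centroid of the connector's
#' postsynaptic sites), and one postsynaptic site per row for the
#' postsynaptic neuron.
#'
#' @param connectors Connector table (see [read_connectors()]).
#' @return Long tibble with columns `neuron_id`, `x`, `y`, `z`, `polarity`
#'   (`"pre"` or `"post"`).
#' @export
synapse_clouds <- function(connectors) {
  assert_cols(connectors, c("connector_id", "pre_neuron", "post_neuron", "x", "y", "z"),
    "connector table"
  )
  has_pre_pos <- all(c("pre_x", "pre_y", "pre_z") %in% names(connectors))
  pre <- connectors %>%
    dplyr::group_by(.data$connector_id, neuron_id = as.character(.data$pre_neuron)) %>%
    {
      if (has_pre_pos) {
        dplyr::summarise(., x = .data$pre_x[1L], y = .data$pre_y[1L], z = .data$pre_z[1L], .groups = "drop")
      } else {
        dplyr::summarise(., x = mean(.data$x), y = mean(.data$y), z = mean(.data$z), .groups = "drop")
      }
    } %>%
    dplyr::transmute(.data$neuron_id, .data$x, .data$y, .data$z, polarity = "pre")
  post <- connectors %>%
    dplyr::transmute(
      neuron_id = as.character(.data$post_neuron),
      .data$x, .data$y, .data$z, polarity = "post"
    )
  dplyr::bind_rows(pre, post) %>% dplyr::arrange(.data$neuron_id)
}

#' Local synapse density around each site of a cloud
#'
#' Counts, for every site, the same-polarity sites of the same cloud within
#' Euclidean radius `omega`, inclusive of the site itself (so the count is
#' always at least 1). This is the density term that down-weights matches
#' between sites sitting in very differently crowded neighbourhoods.
#'
#' @param cloud Tibble with columns `x`, `y`, `z`, `polarity` (one neuron's
#'   sites).
#' @param omega Radius, nm (default 2000).
#' @return Integer vector of counts, aligned with the rows of `cloud`.
#' @export
local_density <- function(cloud, omega = 2000) {
  assert_cols(cloud, c("x", "y", "z", "polarity"), "synapse cloud")
  assert_scalar_pos(omega, "omega")
  out <- integer(nrow(cloud))
  for (p in unique(cloud$polarity)) {
    rows <- which(cloud$polarity == p)
    pts <- as_xyz_matrix(cloud[rows, ])
    out[rows] <- nn_radius_count(pts, pts, omega)
  }
  out
}

#' Synapse placement similarity between two neurons
#'
#' For each site s of neuron i, the nearest site k of neuron j *of the same
#' polarity* contributes
#' `f = exp(-d_sk^2 / (2 sigma^2)) * exp(-|n_is - n_jk| / (n_is + n_jk))`,
#' where `n_is`, `n_jk` count same-polarity sites within radius `omega` of s
#' and k in their own clouds. The score is the mean of f over all sites of
#' i, so it is asymmetric in general; it is 1 exactly for a
#' self-comparison. Sites of i with no same-polarity counterpart in j
#' contribute 0 (`unmatched = "zero"`) or are dropped from the mean
#' (`unmatched = "skip"`). The reference analysis uses
#' `sigma = omega = 2000` nm.
#'
#' @param cloud_i,cloud_j Site tibbles (`x`, `y`, `z`, `polarity`), e.g.
#'   slices of [synapse_clouds()] output.
#' @param sigma Gaussian distance scale, nm.
#' @param omega Density-count radius, nm.
#' @param unmatched How sites of i without a same-polarity site in j enter
#'   the mean.
#' @return Scalar score in \[0, 1\].
#' @export
synapse_similarity <- function(cloud_i, cloud_j, sigma = 2000, omega = 2000,
                               unmatched = c("zero", "skip")) {
  unmatched <- match.arg(unmatched)
  assert_scalar_pos(sigma, "sigma")
  assert_scalar_pos(omega, "omega")
  assert_cols(cloud_i, c("x", "y", "z", "polarity"), "cloud_i")
  assert_cols(cloud_j, c("x", "y", "z", "polarity"), "cloud_j")
  if (nrow(cloud_i) == 0L || nrow(cloud_j) == 0L) abort("synapse clouds must be non-empty")
  if (!any(cloud_j$polarity %in% cloud_i$polarity)) {
    abort("cloud_j has no site matching any polarity present in cloud_i")
  }
  synapse_similarity_impl(
    as_xyz_matrix(cloud_i), cloud_i$polarity, local_density(cloud_i, omega),
    as_xyz_matrix(cloud_j), cloud_j$polarity, local_density(cloud_j, omega),
    sigma, unmatched
  )
}

# Core kernel on pre-extracted matrices/densities (reused by the matrix
# routine so densities are computed once per cloud).
synapse_similarity_impl <- function(pts_i, pol_i, dens_i, pts_j, pol_j, dens_j,
                                    sigma, unmatched) {
  f <- rep(NA_real_, length(pol_i))
  for (p in unique(pol_i)) {
    rows_i <- which(pol_i == p)
    rows_j <- which(pol_j == p)
    if (length(rows_j) == 0L) {
      if (unmatched == "zero") f[rows_i] <- 0
      next
    }
    nn <- nn_nearest(pts_i[rows_i, , drop = FALSE], pts_j[rows_j, , drop = FALSE])
    n_is <- dens_i[rows_i]
    n_jk <- dens_j[rows_j][nn$index]
    f[rows_i] <- exp(-nn$dist^2 / (2 * sigma^2)) *
      exp(-abs(n_is - n_jk) / (n_is + n_jk))
  }
  f <- f[!is.na(f)]
  if (length(f) == 0L) abort("no matched sites between clouds (unmatched = \"skip\")")
  mean(f)
}

#' Pairwise synapse similarity matrix
#'
#' @param clouds Either a long tibble with a `neuron_id` column (as from
#'   [synapse_clouds()]) or a named list of per-neuron site tibbles.
#' @param ids Optional subset/order of neuron ids to score.
#' @param sigma,omega,unmatched See [synapse_similarity()].
#' @param symmetrize Average the matrix with its transpose (default `TRUE`).
#' @return Square numeric matrix with unit diagonal.
#' @export
synapse_similarity_matrix <- function(clouds, ids = NULL, sigma = 2000, omega = 2000,
                                      unmatched = c("zero", "skip"), symmetrize = TRUE) {
  unmatched <- match.arg(unmatched)
  if (is.data.frame(clouds)) {
    assert_cols(clouds, c("neuron_id", "x", "y", "z", "polarity"), "clouds")
    clouds <- split(
      clouds[, c("x", "y", "z", "polarity")],
      as.character(clouds$neuron_id)
    )
  }
  if (!is.null(ids)) {
    missing <- setdiff(ids, names(clouds))
    if (length(missing) > 0L) {
      abort(sprintf("no synapse sites for neuron(s): %s", paste(missing, collapse = ", ")))
    }
    clouds <- clouds[as.character(ids)]
  }
  n <- length(clouds)
  if (n < 2L) abort("need at least two clouds to build a matrix")
  labels <- names(clouds)
  pts <- lapply(clouds, as_xyz_matrix)
  pol <- lapply(clouds, function(cl) cl$polarity)
  dens <- lapply(clouds, local_density, omega = omega)
  m <- matrix(1, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        m[i, j] <- synapse_similarity_impl(
          pts[[i]], pol[[i]], dens[[i]],
          pts[[j]], pol[[j]], dens[[j]],
          sigma, unmatched
        )
      }
    }
  }
  if (symmetrize) m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}
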
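# Fixture builders used across test files. Everything is generated in code
# under fixed seeds.

rand_dotprops <- function(n = 20, scale = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pts <- matrix(stats::runif(n * 3, 0, scale), ncol = 3)
  tg <- matrix(stats::rnorm(n * 3), ncol = 3)
  dotprops(pts, tg)
}

rand_cloud <- function(n = 15, scale = 5000, seed = NULL, polarities = c("pre", "post")) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    x = stats::runif(n, 0, scale),
    y = stats::runif(n, 0, scale),
    z = stats::runif(n, 0, scale),
    polarity = sample(polarities, n, replace = TRUE)
  )
}

# Straight chain skeleton along +x.
chain_skeleton <- function(n = 11, step = 1000) {
  tibble::tibble(
    node_id = seq_len(n),
    parent_id = c(NA_integer_, seq_len(n - 1L)),
    x = (seq_len(n) - 1) * step, y = 0, z = 0
  )
}

# Random directed annotated graph for path / connectivity tests.
rand_graph <- function(n_nodes = 30, p_edge = 0.08, max_w = 4, seed = 1,
                       class_probs = c(sensory = 0.35, interneuron = 0.4, motor = 0.25)) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n_nodes))
  classes <- sample(names(class_probs), n_nodes, replace = TRUE, prob = class_probs)
  pairs <- expand.grid(pre = ids, post = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$pre != pairs$post, ]
  on <- stats::runif(nrow(pairs)) < p_edge
  edges <- tibble::tibble(
    pre = pairs$pre[on], post = pairs$post[on],
    weight = sample.int(max_w, sum(on), replace = TRUE)
  )
  list(
    edges = dplyr::arrange(edges, pre, post),
    annotations = tibble::tibble(neuron_id = ids, class = classes),
    sensory = ids[classes == "sensory"],
    motor = ids[classes == "motor"]
  )
}

# Minimal path_set construction through the public API.
chain_path_set <- function() {
  edges <- tibble::tibble(
    pre = c("S1", "I1"), post = c("I1", "O1"), weight = c(3L, 2L)
  )
  ann <- tibble::tibble(
    neuron_id = c("S1", "I1", "O1"),
    class = c("sensory", "interneuron", "motor")
  )
  enumerate_paths(edges, ann, sources = "S1", target = "O1", threshold = 2)
}
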
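# Shared fixtures and small generators used across test files. Everything is
# built in code; heavier shared computations are cached for the duration of
# one test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, expr, envir = .cache)
  }
  get(key, envir = .cache)
}

# The standard recovery benchmark (shared by the reconstruction, robustness
# and stylized-fact acceptance checks).
std_recovery <- function() {
  cached("recovery", benchmark_recovery(seed = 1))
}

# The standard two-window prediction benchmark.
std_prediction <- function() {
  cached("prediction", benchmark_prediction(seed = 1))
}

tiny_log <- function() {
  tibble::tibble(
    piece_id = c("p1", "p1", "p1"),
    user_id = c("u1", "u2", "u3"),
    parent_id = c(NA, "u1", "u1"),
    timestamp = c(0, 5, 7)
  )
}

# Random digraph with random edge rates in (0, 1]; regenerates until at
# least one edge exists.
random_rates <- function(n, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
      pairs <- pairs[pairs$from != pairs$to, ]
      keep <- runif(nrow(pairs)) < p
      if (any(keep)) break
    }
    edges <- tibble::tibble(
      from = pairs$from[keep], to = pairs$to[keep],
      omega = runif(sum(keep), 0.05, 1)
    )
    contagion_rates(edges, nodes = seq_len(n))
  })
}

# Random *weakly connected* digraph with random rates (for oracle
# cross-validation on tiny instances).
random_connected_rates <- function(n, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
      pairs <- pairs[pairs$from != pairs$to, ]
      keep <- runif(nrow(pairs)) < 0.5
      if (!any(keep)) next
      edges <- pairs[keep, ]
      g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                         vertices = data.frame(name = seq_len(n)))
      if (igraph::is_connected(g, mode = "weak")) break
    }
    contagion_rates(
      tibble::tibble(from = edges$from, to = edges$to,
                     omega = runif(nrow(edges), 0.05, 1)),
      nodes = seq_len(n)
    )
  })
}

# Rank-then-Pearson Spearman, as an independent cross-check of the packaged
# correlation conventions.
spearman_brute <- function(x, y) {
  keep <- is.finite(x) & is.finite(y) & x != 0 & y != 0
  stats::cor(rank(x[keep]), rank(y[keep]), method = "pearson")
}

# Gauge-free comparison of two score sets: edge products I_i * S_j.
edge_products <- function(scores, edges) {
  sc <- tidy(scores)
  i <- match(edges$from, sc$user_id)
  j <- match(edges$to, sc$user_id)
  sc$influence[i] * sc$susceptibility[j]
}
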
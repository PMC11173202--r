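#' Structural centralities of a diffusion network
#'
#' Computes, per node: in- and out-degree over the directed edges, PageRank
#' (damping 0.85) on the recorded edge direction (i -> j meaning i influenced
#' j; set `reverse = TRUE` for the reversed convention), and the k-core index
#' using total degree.
#'
#' @param net A non-empty `diffusion_network`.
#' @param damping PageRank damping factor.
#' @param reverse Reverse edge direction before computing PageRank.
#' @return A tibble `user_id`, `k_in`, `k_out`, `pagerank`, `kcore`.
#' @export
centralities <- function(net, damping = 0.85, reverse = FALSE) {
  nodes <- network_nodes(net)
  if (length(nodes) == 0) {
    abort("Empty network.")
  }
  g <- as_igraph(net)
  pr_g <- if (reverse) igraph::reverse_edges(g) else g
  tibble::tibble(
    user_id = nodes,
    k_in = as.integer(igraph::degree(g, mode = "in")),
    k_out = as.integer(igraph::degree(g, mode = "out")),
    pagerank = as.numeric(igraph::page_rank(pr_g, damping = damping)$vector),
    kcore = as.integer(igraph::coreness(g, mode = "all"))
  )
}

#' Mean scores of a node's in- and out-neighbors
#'
#' For each node: `I_nn_in`, the mean influence of the nodes it reshares from
#' (in-neighbors), and `S_nn_out`, the mean susceptibility of the nodes that
#' reshare from it (out-neighbors). `NA` when the respective neighbor set is
#' empty.
#'
#' @param net A `diffusion_network`.
#' @param scores An `is_scores` object on the same nodes.
#' @return A tibble `user_id`, `I_nn_in`, `S_nn_out`.
#' @export
neighbor_averages <- function(net, scores) {
  sc <- tidy(scores)
  nodes <- network_nodes(net)
  edges <- tibble::as_tibble(net)[c("from", "to")]
  inn <- edges |>
    inner_join(sc[c("user_id", "influence")], by = c("from" = "user_id")) |>
    group_by(.data$to) |>
    summarise(I_nn_in = mean(.data$influence), .groups = "drop")
  out <- edges |>
    inner_join(sc[c("user_id", "susceptibility")], by = c("to" = "user_id")) |>
    group_by(.data$from) |>
    summarise(S_nn_out = mean(.data$susceptibility), .groups = "drop")
  tibble::tibble(user_id = nodes) |>
    left_join(inn, by = c("user_id" = "to")) |>
    left_join(out, by = c("user_id" = "from"))
}

# Per-node table joining scores, centralities and neighbor averages; the
# substrate for all correlation statistics.
node_table <- function(net, scores, cents = NULL) {
  cents <- cents %||% centralities(net)
  tidy(scores) |>
    inner_join(cents, by = "user_id") |>
    left_join(neighbor_averages(net, scores), by = "user_id")
}

# Registry of named correlation statistics over the node table. Each is a
# Spearman correlation restricted to pairs where both values are nonzero
# (and, for neighbor averages, defined).
is_statistic_registry <- list(
  rho_kin_kout = c("k_in", "k_out"),
  rho_kin_influence = c("k_in", "influence"),
  rho_kin_susceptibility = c("k_in", "susceptibility"),
  rho_kout_influence = c("k_out", "influence"),
  rho_kout_susceptibility = c("k_out", "susceptibility"),
  rho_influence_susceptibility = c("influence", "susceptibility"),
  rho_kin_Inn_in = c("k_in", "I_nn_in"),
  rho_kout_Snn_out = c("k_out", "S_nn_out"),
  rho_influence_Snn_out = c("influence", "S_nn_out"),
  rho_susceptibility_Inn_in = c("susceptibility", "I_nn_in")
)

eval_named_statistic <- function(tbl, name) {
  cols <- is_statistic_registry[[name]]
  if (is.null(cols)) {
    abort(sprintf("Unknown statistic `%s`. Available: %s.", name,
                  paste(names(is_statistic_registry), collapse = ", ")))
  }
  spearman_nonzero(tbl[[cols[1]]], tbl[[cols[2]]])
}

#' Pairwise rank correlations between degree and IS scores
#'
#' Spearman correlations for every pair among in-degree, out-degree,
#' influence and susceptibility, each computed over the nodes where both
#' values are nonzero (zero scores and zero degrees carry no information
#' about the traits). Correlations with fewer than 3 qualifying pairs, or a
#' degenerate variable, are reported as `NA`, never 0.
#'
#' @param scores An `is_scores` object.
#' @param cents A centrality tibble from [centralities()].
#' @return A tibble `var1`, `var2`, `rho`, `n_pairs`.
#' @export
node_correlations <- function(scores, cents) {
  tbl <- tidy(scores) |> inner_join(cents, by = "user_id")
  vars <- c("k_in", "k_out", "influence", "susceptibility")
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    r <- spearman_nonzero(tbl[[p[1]]], tbl[[p[2]]])
    tibble::tibble(var1 = p[1], var2 = p[2], rho = r$rho, n_pairs = r$n)
  })
}

#' Assortativity between node properties and neighbor-average scores
#'
#' The four neighbor correlations: in-degree vs mean influence of
#' in-neighbors, out-degree vs mean susceptibility of out-neighbors,
#' influence vs mean susceptibility of out-neighbors, and susceptibility vs
#' mean influence of in-neighbors. Nodes with an empty relevant neighbor set
#' are excluded; the nonzero-pair convention of [node_correlations()]
#' applies.
#'
#' @param net A `diffusion_network`.
#' @param scores An `is_scores` object.
#' @param cents Optional centrality tibble (recomputed when omitted).
#' @return A tibble `statistic`, `rho`, `n_pairs`.
#' @export
neighbor_assortativity <- function(net, scores, cents = NULL) {
  tbl <- node_table(net, scores, cents)
  stats <- c("rho_kin_Inn_in", "rho_kout_Snn_out",
             "rho_influence_Snn_out", "rho_susceptibility_Inn_in")
  purrr::map_dfr(stats, function(s) {
    r <- eval_named_statistic(tbl, s)
    tibble::tibble(statistic = s, rho = r$rho, n_pairs = r$n)
  })
}

#' Degree-preserving rewiring of a rated network
#'
#' Applies directed double-edge swaps: two edges (a -> b), (c -> d) are
#' replaced by (a -> d), (c -> b) when this creates no self-loop or
#' duplicate edge. Every node's in- and out-degree is preserved exactly, and
#' each edge carries its contagion rate (and event count) with its source, so
#' every node's outgoing rate `f_hat` is preserved while the incoming rates
#' are randomized over the degree sequence.
#'
#' @param rates A `contagion_rates` object.
#' @param n_swaps Number of successful swaps to perform (default
#'   `10 * n_edges`).
#' @param seed Optional integer seed.
#' @param max_tries Attempt cap; a warning reports the achieved swap count if
#'   the degree sequence is too constrained.
#' @return A list with the rewired `rates` and `n_swaps_done`.
#' @export
rewire_rates <- function(rates, n_swaps = NULL, seed = NULL,
                         max_tries = NULL) {
  stopifnot(inherits(rates, "contagion_rates"))
  edges <- rates$edges
  m <- nrow(edges)
  if (m < 2) {
    abort("Need at least 2 edges to rewire.")
  }
  n_swaps <- n_swaps %||% (10L * m)
  max_tries <- max_tries %||% (100L * n_swaps)
  from <- edges$from
  to <- edges$to
  key <- function(a, b) paste(a, b, sep = "\r")
  eset <- new.env(parent = emptyenv(), size = 2L * m)
  for (k in key(from, to)) assign(k, TRUE, envir = eset)
  done <- 0L
  tries <- 0L
  with_seed_if(seed, {
    while (done < n_swaps && tries < max_tries) {
      tries <- tries + 1L
      e <- sample.int(m, 2L)
      a <- from[e[1]]; b <- to[e[1]]
      c_ <- from[e[2]]; d <- to[e[2]]
      if (a == c_ || b == d || a == d || c_ == b) next
      k1 <- key(a, d)
      k2 <- key(c_, b)
      if (exists(k1, envir = eset, inherits = FALSE) ||
          exists(k2, envir = eset, inherits = FALSE)) next
      rm(list = c(key(a, b), key(c_, d)), envir = eset)
      assign(k1, TRUE, envir = eset)
      assign(k2, TRUE, envir = eset)
      to[e[1]] <- d
      to[e[2]] <- b
      done <- done + 1L
    }
  })
  if (done < n_swaps) {
    warn(sprintf("Rewiring achieved only %d of %d requested swaps.",
                 done, n_swaps))
  }
  edges$to <- to
  np <- NULL
  if (!all(is.na(rates$nodes$n_pieces))) {
    np <- stats::setNames(rates$nodes$n_pieces,
                          as.character(rates$nodes$user_id))
  }
  out <- contagion_rates(edges, nodes = rates$nodes$user_id, n_pieces = np)
  list(rates = out, n_swaps_done = done)
}

#' Significance of a correlation statistic against rewired networks
#'
#' Empirical two-sided significance test: the named statistic is computed on
#' the observed rated network, then recomputed on `n_reps` degree-preserving
#' rewirings ([rewire_rates()]), *re-running the IS estimation on every
#' rewired instance*. The p-value uses the add-one correction
#' `p = (1 + #(|null| >= |observed|)) / (n_reps + 1)`, so `p` is never 0.
#'
#' @param rates A `contagion_rates` object.
#' @param statistic A name from the statistic registry (see
#'   [node_correlations()] / [neighbor_assortativity()]; e.g.
#'   `"rho_kout_influence"`, `"rho_influence_Snn_out"`) or a function
#'   `f(node_table)` returning a scalar.
#' @param n_reps Number of randomized replicates (>= 20).
#' @param n_swaps Successful swaps per replicate (default `10 * n_edges`).
#' @param seed Optional integer seed for the whole test.
#' @param is_opts List of arguments passed on to [run_is()].
#' @return A `null_result` object with the observed value, the null sample,
#'   and the p-value; see [tidy()] / [glance()].
#' @export
randomized_null <- function(rates, statistic, n_reps = 99L, n_swaps = NULL,
                            seed = NULL, is_opts = list()) {
  if (n_reps < 20) {
    abort("`n_reps` must be at least 20.")
  }
  stat_fun <- if (is.function(statistic)) {
    stat_name <- "custom"
    statistic
  } else {
    stat_name <- statistic
    function(tbl) eval_named_statistic(tbl, statistic)$rho
  }
  evaluate <- function(r) {
    scores <- do.call(run_is, c(list(rates = r, quiet = TRUE), is_opts))
    net <- diffusion_network(r$edges[c("from", "to")],
                             nodes = r$nodes$user_id)
    stat_fun(node_table(net, scores))
  }
  observed <- evaluate(rates)
  with_seed_if(seed, {
    null_values <- vapply(seq_len(n_reps), function(i) {
      rw <- rewire_rates(rates, n_swaps = n_swaps)
      evaluate(rw$rates)
    }, numeric(1))
  })
  ok <- is.finite(null_values)
  if (!all(ok)) {
    warn(sprintf("%d null replicates produced an undefined statistic and were dropped.",
                 sum(!ok)))
  }
  p <- (1 + sum(abs(null_values[ok]) >= abs(observed))) / (sum(ok) + 1)
  structure(
    list(statistic = stat_name, observed = observed,
         null = null_values, p_value = p, n_reps = n_reps),
    class = "null_result"
  )
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("# Randomized-network null: %s\n", x$statistic))
  cat(sprintf("  observed %.4f | null mean %.4f (sd %.4f) over %d replicates | p = %.4f\n",
              x$observed, mean(x$null, na.rm = TRUE),
              stats::sd(x$null, na.rm = TRUE), x$n_reps, x$p_value))
  invisible(x)
}

#' @rdname tidy-spreadis
#' @export
tidy.null_result <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$null), value = x$null)
}

#' @rdname tidy-spreadis
#' @export
glance.null_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, observed = x$observed,
                 null_mean = mean(x$null, na.rm = TRUE),
                 null_sd = stats::sd(x$null, na.rm = TRUE),
                 p_value = x$p_value, n_reps = x$n_reps)
}

#' Quantitative checks of the four stylized influence/susceptibility facts
#'
#' Operationalizes the qualitative regularities reported for influence and
#' susceptibility, each as a continuous statistic with its comparison
#' baseline:
#'
#' * **i** — almost no one is both highly influential and highly
#'   susceptible: the fraction of nodes in both the top-`q` influence and
#'   top-`q` susceptibility sets, against the independence expectation
#'   (approximately `q^2`).
#' * **ii** — influential and non-influential individuals see similar peer
#'   susceptibility: the Kolmogorov-Smirnov distance between the pooled
#'   out-neighbor susceptibility values of top-`q` vs bottom-`q`
#'   influencers (baseline 0 = identical distributions).
#' * **iii** — more people have high influence than high susceptibility:
#'   counts above a common cutoff (`abs_cutoff` times the common mean) after
#'   a symmetric gauge that equates the mean positive influence and
#'   susceptibility; value = high-influence count, baseline =
#'   high-susceptibility count.
#' * **iv** — influentials cluster: the fraction of edges whose two
#'   endpoints are both top-`q` influencers, against the random-placement
#'   expectation `m(m-1) / (n(n-1))` for `m` top nodes.
#'
#' @param scores A converged `is_scores` object.
#' @param net The `diffusion_network` the scores were estimated on.
#' @param q Quantile cutoff defining "high" (default top 10 percent).
#' @param abs_cutoff Multiplier of the common mean used as the absolute
#'   cutoff in fact iii (default 2).
#' @return A tibble `fact`, `statistic`, `value`, `baseline`.
#' @export
stylized_facts <- function(scores, net, q = 0.1, abs_cutoff = 2) {
  stopifnot_scalar_prob(q, "q", open_left = TRUE)
  if (q >= 0.5) {
    abort("`q` must be below 0.5 so top and bottom sets are disjoint.")
  }
  sc <- tidy(scores)
  n <- nrow(sc)
  if (n < 10) {
    abort("Too few nodes for stylized-fact checks.")
  }
  m <- ceiling(q * n)
  top_i <- top_m_by(sc$user_id, sc$influence, m)
  top_s <- top_m_by(sc$user_id, sc$susceptibility, m)
  overlap <- length(intersect(top_i, top_s)) / n

  # (ii): pooled out-neighbor susceptibility of top vs bottom influencers
  bottom_i <- top_m_by(sc$user_id, -sc$influence, m)
  edges <- tibble::as_tibble(net)[c("from", "to")]
  s_of <- stats::setNames(sc$susceptibility, as.character(sc$user_id))
  nb_top <- s_of[as.character(edges$to[edges$from %in% top_i])]
  nb_bot <- s_of[as.character(edges$to[edges$from %in% bottom_i])]
  ks <- if (length(nb_top) >= 3 && length(nb_bot) >= 3) {
    as.numeric(suppressWarnings(ks.test(nb_top, nb_bot))$statistic)
  } else {
    NA_real_
  }

  # (iii): symmetric gauge, then counts above a common absolute cutoff
  pos_i <- sc$influence[sc$influence > 0]
  pos_s <- sc$susceptibility[sc$susceptibility > 0]
  if (length(pos_i) == 0 || length(pos_s) == 0) {
    abort("Degenerate scores: one vector is all zero.")
  }
  cfac <- sqrt(mean(pos_s) / mean(pos_i))
  i_sym <- sc$influence * cfac
  s_sym <- sc$susceptibility / cfac
  common_mean <- mean(i_sym[i_sym > 0])
  cutoff <- abs_cutoff * common_mean
  n_high_i <- sum(i_sym > cutoff)
  n_high_s <- sum(s_sym > cutoff)

  # (iv): co-membership of the top influence set across edges
  both_top <- mean(edges$from %in% top_i & edges$to %in% top_i)
  expected <- (m * (m - 1)) / (n * (n - 1))

  tibble::tibble(
    fact = c("i", "ii", "iii", "iv"),
    statistic = c("top_q_overlap_fraction",
                  "ks_neighbor_susceptibility",
                  "n_high_influence_vs_n_high_susceptibility",
                  "edge_fraction_both_top_influence"),
    value = c(overlap, ks, n_high_i, both_top),
    baseline = c(q^2, 0, n_high_s, expected)
  )
}
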
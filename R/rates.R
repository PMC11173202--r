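#' Construct a contagion-rates object from per-edge rates
#'
#' A `contagion_rates` object holds the per-edge contagion rate
#' `omega[i, j]` (the fraction of i's reshared pieces subsequently reshared by
#' j) together with the node-level aggregates: the outgoing contagion rate
#' `f_hat[i] = sum_j A[i, j] * omega[i, j]` and the incoming contagion rate
#' `g_hat[j] = sum_i A[i, j] * omega[i, j]`. By construction
#' `sum(f_hat) == sum(g_hat) == sum(omega)`.
#'
#' This constructor builds the object directly from an edge table with known
#' `omega` values (useful for hand-built instances and planted benchmarks);
#' [estimate_contagion_rates()] estimates the rates from a cascade log.
#'
#' @param edges Data frame with columns `from`, `to`, `omega` (each in
#'   (0, 1]); an optional `event_count` column is carried along.
#' @param nodes Optional node set covering all endpoints (isolated nodes get
#'   zero rates).
#' @param n_pieces Optional named denominators (distinct pieces reshared per
#'   user); `NA` when unknown.
#' @return A `contagion_rates` object: a list with tibbles `edges`
#'   (`from`, `to`, `omega`, ...) and `nodes`
#'   (`user_id`, `f_hat`, `g_hat`, `n_pieces`).
#' @export
contagion_rates <- function(edges, nodes = NULL, n_pieces = NULL) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("from", "to", "omega") %in% names(edges))) {
    abort("`edges` must have columns `from`, `to` and `omega`.")
  }
  if (nrow(edges) > 0 &&
      (any(!is.finite(edges$omega)) || any(edges$omega <= 0) ||
       any(edges$omega > 1))) {
    abort("Edge rates `omega` must lie in (0, 1].")
  }
  if (any(edges$from == edges$to)) {
    abort("Self-loop in rate edges.")
  }
  if (anyDuplicated(edges[c("from", "to")]) > 0) {
    abort("Duplicate directed edge in rate edges.")
  }
  all_nodes <- sort(unique(c(edges$from, edges$to, nodes)))
  f <- tapply(edges$omega, factor(edges$from, levels = all_nodes), sum)
  g <- tapply(edges$omega, factor(edges$to, levels = all_nodes), sum)
  f[is.na(f)] <- 0
  g[is.na(g)] <- 0
  np <- rep(NA_real_, length(all_nodes))
  if (!is.null(n_pieces)) {
    np <- as.numeric(n_pieces[match(all_nodes, names(n_pieces))])
  }
  nodes_tbl <- tibble::tibble(
    user_id = all_nodes,
    f_hat = as.numeric(f),
    g_hat = as.numeric(g),
    n_pieces = np
  )
  structure(
    list(edges = arrange(edges, .data$from, .data$to), nodes = nodes_tbl),
    class = "contagion_rates"
  )
}

#' @export
print.contagion_rates <- function(x, ...) {
  cat(sprintf(
    "# Contagion rates: %d nodes, %d edges, total rate %.4f\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$omega)))
  print(x$nodes, ...)
  invisible(x)
}

#' @rdname tidy-spreadis
#' @export
tidy.contagion_rates <- function(x, ...) {
  x$nodes
}

#' Estimate per-edge and per-node contagion rates from a cascade log
#'
#' For each recorded edge i -> j, the contagion rate is estimated as
#' `omega[i, j] =` (number of distinct pieces j reshared from i) / (number of
#' distinct pieces i participated in, as root or resharer). The node-level
#' outgoing and incoming rates `f_hat` and `g_hat` are the row and column sums
#' of `omega` over the network's edges.
#'
#' @param events An event-log data frame.
#' @param net Optional `diffusion_network` consistent with `events`; rebuilt
#'   from the log when omitted.
#' @return A `contagion_rates` object.
#' @examples
#' log <- tibble::tibble(
#'   piece_id = c("p1", "p1", "p2", "p2", "p3", "p4"),
#'   user_id = c("a", "b", "a", "b", "a", "a"),
#'   parent_id = c(NA, "a", NA, "a", NA, NA),
#'   timestamp = c(0, 1, 2, 3, 4, 5)
#' )
#' # a reshared 4 pieces, b reshared 2 of them from a: omega = 0.5
#' estimate_contagion_rates(log)$edges
#' @export
estimate_contagion_rates <- function(events, net = NULL) {
  events <- validate_event_log(events)
  if (is.null(net)) {
    net <- build_diffusion_network(events)
  }
  # Rows are unique per (piece, user), so per-user row counts are distinct
  # piece counts and per-(parent, user) counts are distinct joint pieces.
  n_pieces_tbl <- count(events, .data$user_id, name = "n_pieces")
  n_pieces <- stats::setNames(n_pieces_tbl$n_pieces,
                              as.character(n_pieces_tbl$user_id))
  if (nrow(net) > 0) {
    denom <- n_pieces[as.character(net$from)]
    if (any(is.na(denom) | denom == 0)) {
      abort("Internal inconsistency: a node has outgoing edges but no reshared pieces.")
    }
    edges <- tibble::tibble(
      from = net$from,
      to = net$to,
      omega = as.numeric(net$event_count) / as.numeric(denom),
      event_count = net$event_count
    )
  } else {
    edges <- tibble::tibble(from = network_nodes(net)[0],
                            to = network_nodes(net)[0],
                            omega = numeric(), event_count = integer())
  }
  contagion_rates(edges, nodes = network_nodes(net), n_pieces = n_pieces)
}

# Sparse adjacency and rate vectors aligned to the node ordering of a
# contagion_rates object; used by the fixed-point code.
rates_matrices <- function(rates) {
  nodes <- rates$nodes$user_id
  n <- length(nodes)
  ei <- match(rates$edges$from, nodes)
  ej <- match(rates$edges$to, nodes)
  A <- Matrix::sparseMatrix(i = ei, j = ej, x = 1, dims = c(n, n))
  list(nodes = nodes, n = n, A = A,
       f = rates$nodes$f_hat, g = rates$nodes$g_hat,
       ei = ei, ej = ej, omega = rates$edges$omega)
}
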
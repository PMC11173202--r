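#' Construct a diffusion network object
#'
#' A diffusion network is a simple directed graph stored as a tibble of edges
#' (`from`, `to`, `event_count`) with the full node set (including isolated
#' nodes) kept in an attribute. An edge i -> j exists iff at least one
#' spreading event from i to j was recorded (`event_count >= 1`); networks
#' produced by [generate_network()] start with `event_count = 0` until
#' cascades are simulated on them.
#'
#' @param edges Data frame with columns `from`, `to` and optionally
#'   `event_count` (default 1).
#' @param nodes Vector of node identifiers; defaults to the nodes appearing in
#'   `edges`. Must cover all edge endpoints.
#' @return A `diffusion_network` tibble.
#' @export
diffusion_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    abort("`edges` must have columns `from` and `to`.")
  }
  if (!"event_count" %in% names(edges)) {
    edges$event_count <- rep(1L, nrow(edges))
  }
  if (any(edges$from == edges$to)) {
    abort("Diffusion networks have no self-loops.")
  }
  if (anyDuplicated(edges[c("from", "to")]) > 0) {
    abort("Duplicate directed edge in `edges`.")
  }
  if (any(edges$event_count < 0)) {
    abort("`event_count` must be non-negative.")
  }
  endpoint_ids <- unique(c(edges$from, edges$to))
  if (is.null(nodes)) {
    nodes <- sort(endpoint_ids)
  } else {
    nodes <- sort(unique(nodes))
    if (!all(endpoint_ids %in% nodes)) {
      abort("`nodes` must contain every edge endpoint.")
    }
  }
  edges <- arrange(edges[c("from", "to", "event_count")], .data$from, .data$to)
  structure(edges, nodes = nodes,
            class = c("diffusion_network", class(edges)))
}

#' @export
print.diffusion_network <- function(x, ...) {
  cat(sprintf("# Diffusion network: %d nodes, %d directed edges\n",
              length(network_nodes(x)), nrow(x)))
  NextMethod()
}

#' Node set of a diffusion network
#'
#' @param net A `diffusion_network`.
#' @return The sorted vector of node identifiers, including isolated nodes.
#' @export
network_nodes <- function(net) {
  nodes <- attr(net, "nodes")
  if (is.null(nodes)) {
    nodes <- sort(unique(c(net$from, net$to)))
  }
  nodes
}

#' Build the diffusion network from a cascade event log
#'
#' Creates one directed edge per ordered user pair (i, j) for which the log
#' records at least one reshare of j from i, with `event_count` the number of
#' such events. Nodes are all users appearing in any event, so root-only users
#' are kept as isolated nodes.
#'
#' @param events An event-log data frame (see [validate_event_log()]).
#' @return A `diffusion_network`.
#' @examples
#' log <- tibble::tibble(
#'   piece_id = c("p1", "p1", "p2", "p2", "p2"),
#'   user_id = c("u1", "u2", "u1", "u2", "u3"),
#'   parent_id = c(NA, "u1", NA, "u1", "u2"),
#'   timestamp = c(0, 1, 10, 11, 12)
#' )
#' build_diffusion_network(log)
#' @export
build_diffusion_network <- function(events) {
  events <- validate_event_log(events)
  nodes <- unique(events$user_id)
  resh <- events[!is.na(events$parent_id), ]
  if (nrow(resh) == 0) {
    edges <- tibble::tibble(from = nodes[0], to = nodes[0],
                            event_count = integer())
  } else {
    edges <- resh |>
      count(from = .data$parent_id, to = .data$user_id, name = "event_count")
  }
  diffusion_network(edges, nodes = nodes)
}

#' Export a diffusion network edge list as TSV
#'
#' Writes `source<TAB>target<TAB>event_count` with a header line.
#'
#' @param net A `diffusion_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  out <- tibble::tibble(source = net$from, target = net$to,
                        event_count = net$event_count)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# igraph view of the network; vertex names are the (character-coerced) node
# ids so isolated nodes are preserved.
as_igraph <- function(net) {
  nodes <- as.character(network_nodes(net))
  el <- cbind(as.character(net$from), as.character(net$to))
  igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2]),
    directed = TRUE,
    vertices = data.frame(name = nodes)
  )
}
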
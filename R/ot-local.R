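#' Mass distribution on a node's closed neighborhood
#'
#' Places mass `alpha` on node `i` itself and spreads the remaining
#' `1 - alpha` evenly over its neighbors.  With `alpha = 0` (the default used
#' throughout the benchmarks) all mass sits on the neighbors — the one-step
#' transition distribution of a random walker at `i`.
#'
#' @param graph An igraph object.
#' @param node Node name.
#' @param alpha Mass retained at the node itself, in `[0, 1]`.
#' @return A tibble with columns `node` and `mass` (summing to 1), sorted by
#'   node; support is `{i}` plus its neighbors.
#' @export
neighborhood_mass <- function(graph, node, alpha = 0) {
  graph <- as_orc_graph(graph)
  node <- as.character(node)
  stopifnot(length(alpha) == 1, alpha >= 0, alpha <= 1)
  if (!node %in% igraph::V(graph)$name) {
    stop("node '", node, "' not in graph", call. = FALSE)
  }
  nbrs <- igraph::neighbors(graph, node)$name
  if (length(nbrs) == 0) {
    stop("node '", node, "' is isolated: no neighborhood mass distribution",
         call. = FALSE)
  }
  out <- tibble::tibble(
    node = c(node, nbrs),
    mass = c(alpha, rep((1 - alpha) / length(nbrs), length(nbrs)))
  )
  dplyr::arrange(out, .data$node)
}

# low-level constructor: left/right node name vectors, cost matrix (left x
# right), and source/sink mass vectors aligned with them
new_bipartite_problem <- function(left, right, cost, source, sink,
                                  edge = c(NA_character_, NA_character_)) {
  stopifnot(nrow(cost) == length(left), ncol(cost) == length(right),
            length(source) == length(left), length(sink) == length(right))
  if (abs(sum(source) - 1) > 1e-9 || abs(sum(sink) - 1) > 1e-9) {
    stop("source and sink masses must each sum to 1", call. = FALSE)
  }
  if (any(cost < 0) || any(!is.finite(cost))) {
    stop("costs must be finite and nonnegative", call. = FALSE)
  }
  dimnames(cost) <- list(left, right)
  structure(list(left = left, right = right, cost = cost,
                 source = as.numeric(source), sink = as.numeric(sink),
                 edge = edge),
            class = "bipartite_ot_problem")
}

#' Local bipartite optimal-transport problem for an edge
#'
#' For an edge (i, j) of the graph, builds the complete bipartite problem on
#' which the transport between the two neighborhood distributions is solved:
#' left nodes are \eqn{N(i) \cup \{i\}}, right nodes \eqn{N(j) \cup \{j\}},
#' and the cost of a left-right pair is the weighted shortest-path distance
#' between the two nodes in the graph (0 when they are the same node).  The
#' source and sink are the neighborhood masses of i and j.
#'
#' @inheritParams neighborhood_mass
#' @param i,j Endpoints of an existing edge.
#' @param dist Optional precomputed all-pairs distance matrix (as from
#'   [shortest_path_distance()]); recomputed if missing.
#' @return A `bipartite_ot_problem` object with elements `left`, `right`,
#'   `cost`, `source`, `sink`.
#' @export
build_local_ot_problem <- function(graph, i, j, alpha = 0, dist = NULL) {
  graph <- as_orc_graph(graph)
  i <- as.character(i); j <- as.character(j)
  if (!igraph::are_adjacent(graph, i, j)) {
    stop("(", i, ", ", j, ") is not an edge of the graph", call. = FALSE)
  }
  mi <- neighborhood_mass(graph, i, alpha)
  mj <- neighborhood_mass(graph, j, alpha)
  left <- sort(unique(c(i, igraph::neighbors(graph, i)$name)))
  right <- sort(unique(c(j, igraph::neighbors(graph, j)$name)))
  if (is.null(dist)) {
    dist <- igraph::distances(graph, v = left, to = right,
                              weights = igraph::E(graph)$weight)
  } else {
    dist <- dist[left, right, drop = FALSE]
  }
  if (any(!is.finite(dist))) {
    stop("neighborhoods of ", i, " and ", j, " are not connected in the graph",
         call. = FALSE)
  }
  source <- mi$mass[match(left, mi$node)]
  source[is.na(source)] <- 0
  sink <- mj$mass[match(right, mj$node)]
  sink[is.na(sink)] <- 0
  new_bipartite_problem(left, right, unname(dist), source, sink, edge = c(i, j))
}

#' @export
print.bipartite_ot_problem <- function(x, ...) {
  cat("<bipartite_ot_problem>", length(x$left), "x", length(x$right),
      "nodes")
  if (!is.na(x$edge[1])) cat("  [edge", x$edge[1], "-", x$edge[2], "]")
  cat("\n")
  invisible(x)
}

#' Tidy a bipartite transport problem into a long table
#'
#' One row per left-right pair with its cost and the endpoint masses — the
#' debug/export form of the problem.
#'
#' @param x A `bipartite_ot_problem`.
#' @param ... Unused.
#' @return A tibble with columns `left`, `right`, `cost`, `source_mass`,
#'   `sink_mass`.
#' @export
tidy.bipartite_ot_problem <- function(x, ...) {
  grid <- tidyr::expand_grid(left = x$left, right = x$right)
  grid$cost <- as.vector(t(x$cost))
  grid$source_mass <- x$source[match(grid$left, x$left)]
  grid$sink_mass <- x$sink[match(grid$right, x$right)]
  grid
}
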
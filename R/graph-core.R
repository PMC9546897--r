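#' Coerce and validate a weighted undirected graph
#'
#' Normalizes any igraph object into the form the package works with: an
#' undirected simple graph with character vertex names and strictly positive
#' edge weights.  Self-loops are dropped, duplicate edges are collapsed
#' keeping the first weight seen, and missing weights default to 1.
#'
#' @param graph An igraph object.
#' @return An undirected simple igraph object with `name` (character) vertex
#'   attribute and positive `weight` edge attribute.
#' @export
as_orc_graph <- function(graph) {
  if (!igraph::is_igraph(graph)) {
    stop("`graph` must be an igraph object", call. = FALSE)
  }
  if (igraph::vcount(graph) == 0) {
    stop("graph is empty (no nodes)", call. = FALSE)
  }
  if (igraph::is_directed(graph)) {
    graph <- igraph::as_undirected(graph, mode = "collapse",
                                   edge.attr.comb = list(weight = "first", "ignore"))
  }
  if (is.null(igraph::vertex_attr(graph, "name"))) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  } else {
    igraph::V(graph)$name <- as.character(igraph::V(graph)$name)
  }
  if (anyDuplicated(igraph::V(graph)$name)) {
    stop("duplicate node identifiers", call. = FALSE)
  }
  if (is.null(igraph::edge_attr(graph, "weight"))) {
    igraph::E(graph)$weight <- rep(1, igraph::ecount(graph))
  }
  graph <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE,
                            edge.attr.comb = list(weight = "first", "ignore"))
  w <- igraph::E(graph)$weight
  if (igraph::ecount(graph) > 0 && (anyNA(w) || any(w <= 0))) {
    stop("all edge weights must be strictly positive", call. = FALSE)
  }
  graph
}

#' Read a graph from GML or edge-list file
#'
#' Supports the GML dialect of Newman's netdata collection (node `id`/`label`,
#' edge `source`/`target`/`value`) and plain edge lists with two or three
#' whitespace- or comma-separated columns `u v [w]`.  Missing weights default
#' to 1; self-loops are dropped and duplicate edges collapsed keeping the
#' first weight.
#'
#' @param path Path to the file.
#' @param format `"gml"`, `"edgelist"`, or `"auto"` (default: decide from the
#'   file extension, falling back to edge list).
#' @return An igraph object (see [as_orc_graph()]).
#' @export
read_graph_file <- function(path, format = c("auto", "gml", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.gml$", path, ignore.case = TRUE)) "gml" else "edgelist"
  }
  if (format == "gml") {
    g <- tryCatch(igraph::read_graph(path, format = "gml"),
                  error = function(e) {
                    stop("GML parse failure in '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
    lab <- igraph::vertex_attr(g, "label")
    if (!is.null(lab) && !anyDuplicated(as.character(lab))) {
      igraph::V(g)$name <- as.character(lab)
    } else if (!is.null(igraph::vertex_attr(g, "id"))) {
      igraph::V(g)$name <- as.character(igraph::vertex_attr(g, "id"))
    }
    val <- igraph::edge_attr(g, "value")
    if (is.null(igraph::edge_attr(g, "weight")) && !is.null(val)) {
      igraph::E(g)$weight <- as.numeric(val)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    rows <- which(keep)
    if (length(rows) == 0) stop("empty graph in '", path, "'", call. = FALSE)
    parts <- strsplit(trimws(lines[rows]), "[,[:space:]]+")
    nf <- lengths(parts)
    bad <- which(nf < 2 | nf > 3)
    if (length(bad) > 0) {
      stop("edge list parse failure in '", path, "' at line ", rows[bad[1]],
           ": expected 'u v [w]', got '", lines[rows[bad[1]]], "'", call. = FALSE)
    }
    u <- vapply(parts, `[`, "", 1)
    v <- vapply(parts, `[`, "", 2)
    w <- vapply(parts, function(p) if (length(p) == 3) p[3] else "1", "")
    wn <- suppressWarnings(as.numeric(w))
    if (anyNA(wn)) {
      bad <- which(is.na(wn))[1]
      stop("edge list parse failure in '", path, "' at line ", rows[bad],
           ": non-numeric weight '", w[bad], "'", call. = FALSE)
    }
    g <- igraph::graph_from_data_frame(
      data.frame(from = u, to = v, weight = wn, stringsAsFactors = FALSE),
      directed = FALSE)
  }
  as_orc_graph(g)
}

#' Write a graph to GML or edge-list file
#'
#' @param graph An igraph object.
#' @param path Output path.
#' @param format `"gml"` or `"edgelist"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path, format = c("auto", "gml", "edgelist")) {
  format <- match.arg(format)
  graph <- as_orc_graph(graph)
  if (format == "auto") {
    format <- if (grepl("\\.gml$", path, ignore.case = TRUE)) "gml" else "edgelist"
  }
  el <- igraph::as_edgelist(graph, names = TRUE)
  w <- igraph::E(graph)$weight
  if (format == "edgelist") {
    writeLines(sprintf("%s %s %.17g", el[, 1], el[, 2], w), path)
  } else {
    nm <- igraph::V(graph)$name
    idx <- seq_along(nm) - 1L
    node_block <- sprintf("  node\n  [\n    id %d\n    label \"%s\"\n  ]", idx, nm)
    src <- match(el[, 1], nm) - 1L
    tgt <- match(el[, 2], nm) - 1L
    edge_block <- sprintf(
      "  edge\n  [\n    source %d\n    target %d\n    value %.17g\n  ]",
      src, tgt, w)
    writeLines(c("graph", "[", node_block, edge_block, "]"), path)
  }
  invisible(path)
}

#' Weighted shortest-path distances
#'
#' Edge weights are interpreted as lengths.  Returns `Inf` for node pairs in
#' different connected components.
#'
#' @param graph An igraph object.
#' @param from,to Optional node names.  If both are given, a single number is
#'   returned; if both are `NULL`, the full symmetric distance matrix.
#' @return A number or a numeric matrix with node names as dimnames.
#' @export
shortest_path_distance <- function(graph, from = NULL, to = NULL) {
  graph <- as_orc_graph(graph)
  if (is.null(from) != is.null(to)) {
    stop("supply both `from` and `to`, or neither", call. = FALSE)
  }
  if (is.null(from)) {
    return(igraph::distances(graph, weights = igraph::E(graph)$weight))
  }
  d <- igraph::distances(graph, v = as.character(from), to = as.character(to),
                         weights = igraph::E(graph)$weight)
  as.numeric(d)
}

#' Newman modularity of a partition
#'
#' Weighted Newman modularity \eqn{Q = \sum_c (e_{cc} - a_c^2)}, where
#' \eqn{e_{cc}} is the fraction of edge weight inside community c and
#' \eqn{a_c} the fraction of weighted degree attached to it.  On unweighted
#' graphs this reduces to the standard definition.
#'
#' @param graph An igraph object.
#' @param partition A partition: tibble/data.frame with columns `node` and
#'   `community`, or a named vector of labels.  Must cover every node.
#' @return A single number.
#' @export
graph_modularity <- function(graph, partition) {
  graph <- as_orc_graph(graph)
  partition <- as_partition(partition)
  membership <- partition_membership(graph, partition)
  igraph::modularity(graph, membership, weights = igraph::E(graph)$weight)
}

#' Normalize edge weights to unit total
#'
#' Divides every edge weight by the sum of all weights, preserving ratios.
#'
#' @param graph An igraph object with at least one edge.
#' @return The graph with weights summing to 1.
#' @export
normalize_weights <- function(graph) {
  graph <- as_orc_graph(graph)
  if (igraph::ecount(graph) == 0) stop("graph has no edges", call. = FALSE)
  total <- sum(igraph::E(graph)$weight)
  if (total <= 0) stop("total edge weight must be positive", call. = FALSE)
  igraph::E(graph)$weight <- igraph::E(graph)$weight / total
  graph
}

#' Summary statistics of a graph
#'
#' Node and edge counts, average degree (2|E|/|V|), mean normalized
#' shortest-path betweenness centrality, and mean unweighted local clustering
#' coefficient (nodes of degree < 2 counted as 0).  Betweenness and
#' clustering are topological: edge weights are ignored, the convention under
#' which the classic social-network datasets are usually tabulated.
#'
#' @param graph An igraph object.
#' @return A one-row tibble with columns `n_nodes`, `n_edges`, `avg_degree`,
#'   `avg_betweenness`, `avg_clustering`.
#' @export
graph_stats <- function(graph) {
  graph <- as_orc_graph(graph)
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  btw <- igraph::betweenness(graph, directed = FALSE, weights = NA,
                             normalized = TRUE)
  clust <- igraph::transitivity(graph, type = "localundirected",
                                isolates = "zero", weights = NA)
  tibble::tibble(
    n_nodes = n,
    n_edges = m,
    avg_degree = 2 * m / n,
    avg_betweenness = mean(btw),
    avg_clustering = mean(clust)
  )
}
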
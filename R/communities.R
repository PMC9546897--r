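#' Network surgery at a weight threshold
#'
#' Removes every edge whose weight exceeds `threshold` (after the Ricci flow
#' the longest edges are the negatively curved bridges) and reads the
#' partition off the connected components of what remains.  Modularity is
#' evaluated against `score_graph` — by default the graph being cut, but in
#' the detection pipeline the original input graph, so that community
#' quality is judged on the network as observed, not on the flowed weights.
#'
#' @param graph An igraph object (typically a flowed snapshot).
#' @param threshold Finite cut weight; edges with `weight > threshold` are
#'   removed.
#' @param score_graph Graph on which the partition's modularity is computed
#'   (same node set as `graph`).
#' @return A `surgery_result`: list with `partition` (tibble), `threshold`,
#'   `modularity`, `n_cut_edges`.
#' @export
surgery <- function(graph, threshold, score_graph = graph) {
  graph <- as_orc_graph(graph)
  stopifnot(is.finite(threshold))
  drop <- which(igraph::E(graph)$weight > threshold)
  cut <- igraph::delete_edges(graph, drop)
  comp <- igraph::components(cut)
  partition <- as_partition(tibble::tibble(
    node = igraph::V(cut)$name,
    community = as.character(comp$membership)))
  structure(list(partition = partition, threshold = threshold,
                 modularity = graph_modularity(score_graph, partition),
                 n_cut_edges = length(drop)),
            class = "surgery_result")
}

#' @export
print.surgery_result <- function(x, ...) {
  cat("<surgery_result>", length(unique(x$partition$community)),
      "communities, Q =", signif(x$modularity, 4), ", cut",
      x$n_cut_edges, "edges at threshold", signif(x$threshold, 4), "\n")
  invisible(x)
}

#' Modularity-maximizing surgery
#'
#' Scans candidate thresholds — the midpoints between consecutive distinct
#' edge weights, plus the maximum weight (cut nothing) — and keeps the cut
#' with the highest modularity.  Ties are broken toward fewer communities.
#'
#' @inheritParams surgery
#' @return The best `surgery_result`.
#' @export
best_surgery <- function(graph, score_graph = graph) {
  graph <- as_orc_graph(graph)
  if (igraph::ecount(graph) == 0) stop("graph has no edges", call. = FALSE)
  el <- igraph::as_edgelist(graph, names = TRUE)
  el_score <- igraph::as_edgelist(score_graph, names = TRUE)
  if (identical(igraph::V(graph)$name, igraph::V(score_graph)$name) &&
      identical(el, el_score)) {
    # same topology: incremental union-find scan over all thresholds
    scan <- surgery_scan_cpp(
      igraph::as_edgelist(graph, names = FALSE) - 1L,
      igraph::E(graph)$weight, igraph::E(score_graph)$weight,
      igraph::vcount(graph))
    best <- which(scan$modularity > max(scan$modularity) - 1e-12)
    best <- best[order(scan$n_communities[best],
                       -scan$threshold[best])][1]
    return(surgery(graph, scan$threshold[best], score_graph))
  }
  w <- sort(unique(igraph::E(graph)$weight))
  cands <- if (length(w) == 1) w else c((w[-length(w)] + w[-1]) / 2, w[length(w)])
  results <- lapply(cands, function(th) surgery(graph, th, score_graph))
  q <- vapply(results, `[[`, 0, "modularity")
  nc <- vapply(results, function(r) length(unique(r$partition$community)), 0L)
  best <- which(q > max(q) - 1e-12)
  best <- best[order(nc[best], -cands[best])][1]
  results[[best]]
}

#' Detect communities by curvature-driven Ricci flow
#'
#' End-to-end pipeline: runs [run_flow()] for `max_iter` iterations,
#' applies the modularity-maximizing surgery to every snapshot, and returns
#' the snapshot partition with the highest modularity (`selection =
#' "modularity"`, the deployment default — no ground truth needed) or the
#' highest adjusted Rand index against `truth` (`selection = "ari"`, the
#' benchmarking protocol).  The number of communities is not an input:
#' it emerges from the surgery.  Isolated nodes are returned as singleton
#' communities.
#'
#' @inheritParams run_flow
#' @param selection `"modularity"` or `"ari"`.
#' @param truth Ground-truth partition, required for `selection = "ari"`.
#' @return A `community_fit` object: `partition` (tibble over all nodes),
#'   `trace` (the `flow_trace`), `iteration` selected, and the selection
#'   `score`.  See [tidy.community_fit()] / [glance.community_fit()].
#' @export
detect_communities <- function(graph, beta = 1, alpha = 0, max_iter = 15,
                               selection = c("modularity", "ari"),
                               truth = NULL, config = NULL,
                               solver = c("dmk", "sinkhorn"),
                               sinkhorn_reg = 1e-2) {
  selection <- match.arg(selection)
  solver <- match.arg(solver)
  graph <- as_orc_graph(graph)
  if (selection == "ari") {
    if (is.null(truth)) {
      stop('`selection = "ari"` requires a ground-truth partition in `truth`',
           call. = FALSE)
    }
    truth <- as_partition(truth)
  }
  iso <- igraph::V(graph)$name[igraph::degree(graph) == 0]
  core <- if (length(iso) > 0) {
    igraph::delete_vertices(graph, iso)
  } else {
    graph
  }
  trace <- run_flow(core, beta = beta, alpha = alpha, max_iter = max_iter,
                    config = config, solver = solver,
                    sinkhorn_reg = sinkhorn_reg)

  complete <- function(p) {
    if (length(iso) == 0) return(p)
    as_partition(dplyr::bind_rows(
      p, tibble::tibble(node = iso, community = paste0("isolated_", iso))))
  }
  parts <- lapply(trace$snapshots, function(s) complete(s$surgery$partition))
  scores <- if (selection == "modularity") {
    vapply(trace$snapshots, function(s) s$surgery$modularity, 0)
  } else {
    vapply(parts, function(p) adjusted_rand_index(p, truth), 0)
  }
  pick <- which.max(scores)
  structure(list(partition = parts[[pick]], trace = trace,
                 selection = selection,
                 iteration = trace$snapshots[[pick]]$iteration,
                 score = scores[pick], scores = scores,
                 beta = trace$beta, solver = solver, graph = graph),
            class = "community_fit")
}

#' @export
print.community_fit <- function(x, ...) {
  cat("<community_fit>", length(unique(x$partition$community)),
      "communities over", nrow(x$partition), "nodes\n")
  cat("  selected iteration", x$iteration, "by", x$selection, "=",
      signif(x$score, 4), " (beta =", x$beta, ",", x$solver, "solver)\n")
  invisible(x)
}

#' Partition of a community fit
#'
#' @param x A `community_fit` from [detect_communities()].
#' @param ... Unused.
#' @return The partition tibble (`node`, `community`).
#' @export
tidy.community_fit <- function(x, ...) x$partition

#' One-row summary of a community fit
#'
#' @param x A `community_fit`.
#' @param ... Unused.
#' @return A tibble with the number of communities, selected iteration,
#'   selection score, and modularity on the input graph.
#' @export
glance.community_fit <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$partition),
    n_communities = length(unique(x$partition$community)),
    iteration = x$iteration,
    selection = x$selection,
    score = x$score,
    modularity = graph_modularity(x$graph, x$partition),
    beta = x$beta,
    solver = x$solver
  )
}

#' Plot community sizes of a fit
#'
#' @param object A `community_fit`.
#' @param ... Unused.
#' @return A ggplot bar chart of community sizes.
#' @export
autoplot.community_fit <- function(object, ...) {
  sizes <- dplyr::count(object$partition, .data$community, name = "size")
  sizes <- dplyr::arrange(sizes, dplyr::desc(.data$size))
  sizes$community <- factor(sizes$community, levels = sizes$community)
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$community, y = .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "community", y = "nodes",
                  title = paste0(nrow(sizes), " communities (beta = ",
                                 object$beta, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
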
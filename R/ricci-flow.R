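#' Beta-Ollivier-Ricci curvature of one edge
#'
#' \eqn{\kappa_\beta(i,j) = 1 - W_\beta(m_i, m_j)/d_{ij}}, where
#' \eqn{W_\beta} is the transport cost between the endpoint neighborhood
#' distributions (solved by [solve_dmk()] on the local bipartite problem)
#' and \eqn{d_{ij}} the weighted shortest-path distance between i and j —
#' which can be smaller than the edge's own weight.  Positive curvature
#' marks intra-community edges, negative curvature bridges.
#'
#' @param graph An igraph object.
#' @param i,j Endpoints of an existing edge.
#' @param beta Traffic rate in `(0, 2]`; ignored if `config` is supplied.
#' @param alpha Mass retained at each endpoint (see [neighborhood_mass()]).
#' @param config Optional [dmk_config()]; defaults to `dmk_config(beta = beta)`.
#' @param solver `"dmk"` (default) or `"sinkhorn"` — the latter computes the
#'   transport cost with entropically regularized 1-Wasserstein iterations
#'   (the OTDSinkhorn-style baseline) and ignores `beta`.
#' @param sinkhorn_reg Regularization for `solver = "sinkhorn"`.
#' @return A single number `<= 1`.
#' @export
edge_curvature <- function(graph, i, j, beta = 1, alpha = 0, config = NULL,
                           solver = c("dmk", "sinkhorn"), sinkhorn_reg = 1e-2) {
  solver <- match.arg(solver)
  graph <- as_orc_graph(graph)
  config <- if (is.null(config)) dmk_config(beta = beta) else as_dmk_config(config)
  problem <- build_local_ot_problem(graph, i, j, alpha)
  d_ij <- shortest_path_distance(graph, i, j)
  if (!is.finite(d_ij) || d_ij <= 0) {
    stop("endpoints must be connected at positive distance", call. = FALSE)
  }
  w <- if (solver == "dmk") {
    solve_dmk(problem, config)$cost
  } else {
    sinkhorn_transport_cost(problem, reg = sinkhorn_reg)
  }
  1 - w / d_ij
}

# Curvature of every edge, plus the warm-start state used across Ricci flow
# iterations.  `dist` is the all-pairs shortest-path matrix on the current
# weights; `warm` is the per-edge conductivity list from the previous
# iteration (NULL for cold start).
curvature_core <- function(graph, beta, alpha, config, solver, sinkhorn_reg,
                           dist = NULL, warm = NULL) {
  if (igraph::ecount(graph) == 0) {
    stop("graph has no edges", call. = FALSE)
  }
  if (is.null(dist)) {
    dist <- igraph::distances(graph, weights = igraph::E(graph)$weight)
  }
  el_idx <- igraph::as_edgelist(graph, names = FALSE)
  el <- igraph::as_edgelist(graph, names = TRUE)
  m <- nrow(el_idx)
  d_edge <- dist[el_idx]
  if (solver == "dmk") {
    nbrs <- lapply(igraph::adjacent_vertices(graph, igraph::V(graph)),
                   function(v) as.integer(v) - 1L)
    res <- dmk_wasserstein_batch_cpp(
      matrix(as.integer(el_idx - 1L), ncol = 2), nbrs, dist, alpha,
      config$beta, effective_dt(config), config$tol, config$max_steps,
      config$eps_cost, if (is.null(warm)) list() else warm)
    wass <- res$wasserstein
    converged <- res$converged
    steps <- res$steps
    warm <- res$warm
  } else {
    nm <- igraph::V(graph)$name
    dimnames(dist) <- list(nm, nm)
    wass <- vapply(seq_len(m), function(e) {
      pb <- build_local_ot_problem(graph, el[e, 1], el[e, 2], alpha, dist = dist)
      sinkhorn_transport_cost(pb, reg = sinkhorn_reg)
    }, 0)
    converged <- rep(TRUE, m)
    steps <- rep(NA_integer_, m)
  }
  tbl <- tibble::tibble(
    from = el[, 1], to = el[, 2],
    weight = igraph::E(graph)$weight,
    distance = d_edge,
    wasserstein = wass,
    kappa = 1 - wass / d_edge,
    converged = as.logical(converged),
    steps = as.integer(steps)
  )
  list(curvature = tbl, warm = warm)
}

#' Curvature of every edge
#'
#' @inheritParams edge_curvature
#' @return A tibble with one row per edge: `from`, `to`, `weight`,
#'   `distance`, `wasserstein`, `kappa`, `converged`, `steps`.
#' @export
curvature_all_edges <- function(graph, beta = 1, alpha = 0, config = NULL,
                                solver = c("dmk", "sinkhorn"),
                                sinkhorn_reg = 1e-2) {
  solver <- match.arg(solver)
  graph <- as_orc_graph(graph)
  config <- if (is.null(config)) dmk_config(beta = beta) else as_dmk_config(config)
  curvature_core(graph, beta, alpha, config, solver, sinkhorn_reg)$curvature
}

#' One step of the discrete Ricci flow
#'
#' Each edge's new weight is \eqn{d_{ij}(1 - \kappa_\beta(i,j))} —
#' algebraically the beta-Wasserstein cost between the endpoint
#' distributions — floored at `1e-12` and then normalized so all weights
#' sum to 1.
#'
#' @inheritParams edge_curvature
#' @return A list with `graph` (updated, normalized weights) and
#'   `curvature` (the per-edge tibble used, including the pre-normalization
#'   weight as `weight_new`).
#' @export
ricci_flow_step <- function(graph, beta = 1, alpha = 0, config = NULL,
                            solver = c("dmk", "sinkhorn"),
                            sinkhorn_reg = 1e-2) {
  solver <- match.arg(solver)
  graph <- as_orc_graph(graph)
  config <- if (is.null(config)) dmk_config(beta = beta) else as_dmk_config(config)
  step <- flow_step_core(graph, alpha, config, solver, sinkhorn_reg,
                         warm = NULL)
  list(graph = step$graph, curvature = step$curvature)
}

flow_step_core <- function(graph, alpha, config, solver, sinkhorn_reg, warm,
                           eps_w = 1e-12) {
  core <- curvature_core(graph, config$beta, alpha, config, solver,
                         sinkhorn_reg, warm = warm)
  tbl <- core$curvature
  w_new <- pmax(tbl$distance * (1 - tbl$kappa), eps_w)
  tbl$weight_new <- w_new
  igraph::E(graph)$weight <- w_new / sum(w_new)
  list(graph = graph, curvature = tbl, warm = core$warm)
}

#' Run the iterated Ricci flow
#'
#' Starting from weights \eqn{w^{(0)} = d^{(0)}} (each edge reset to the
#' shortest-path distance between its endpoints, then normalized),
#' repeatedly applies [ricci_flow_step()]: intra-community edges shrink and
#' inter-community ones stretch.  Each snapshot is scored with the
#' modularity-maximizing surgery of [best_surgery()], evaluated against the
#' weights of the input graph.
#'
#' @inheritParams edge_curvature
#' @param max_iter Number of flow iterations (`>= 1`; the benchmarks use 15).
#' @return A `flow_trace` object: snapshots `0..max_iter`, each holding the
#'   (normalized) graph, the curvature table that produced it, and its best
#'   surgery partition.  See [tidy.flow_trace()] and [glance.flow_trace()].
#' @export
run_flow <- function(graph, beta = 1, alpha = 0, max_iter = 15, config = NULL,
                     solver = c("dmk", "sinkhorn"), sinkhorn_reg = 1e-2) {
  solver <- match.arg(solver)
  graph <- as_orc_graph(graph)
  if (max_iter < 1) stop("`max_iter` must be at least 1", call. = FALSE)
  config <- if (is.null(config)) dmk_config(beta = beta) else as_dmk_config(config)
  if (igraph::ecount(graph) == 0) stop("graph has no edges", call. = FALSE)

  score_graph <- graph
  # w(0) = d(0): edge weights reset to current shortest-path distances
  dist0 <- igraph::distances(graph, weights = igraph::E(graph)$weight)
  el_idx <- igraph::as_edgelist(graph, names = FALSE)
  igraph::E(graph)$weight <- dist0[el_idx]
  graph <- normalize_weights(graph)

  snapshots <- vector("list", max_iter + 1)
  snapshots[[1]] <- list(iteration = 0L, graph = graph, curvature = NULL,
                         surgery = best_surgery(graph, score_graph))
  warm <- NULL
  for (t in seq_len(max_iter)) {
    step <- flow_step_core(graph, alpha, config, solver, sinkhorn_reg, warm)
    graph <- step$graph
    warm <- step$warm
    snapshots[[t + 1]] <- list(iteration = t, graph = graph,
                               curvature = step$curvature,
                               surgery = best_surgery(graph, score_graph))
  }
  structure(list(snapshots = snapshots, beta = config$beta, alpha = alpha,
                 solver = solver, score_graph = score_graph),
            class = "flow_trace")
}

#' @export
print.flow_trace <- function(x, ...) {
  g <- glance(x)
  cat("<flow_trace>", nrow(g) - 1, "iterations, beta =", x$beta,
      ", solver =", x$solver, "\n")
  cat("  best modularity", signif(max(g$modularity), 4), "at iteration",
      g$iteration[which.max(g$modularity)], "\n")
  invisible(x)
}

#' Per-edge view of a flow trace
#'
#' @param x A `flow_trace` from [run_flow()].
#' @param ... Unused.
#' @return A tibble with one row per edge and iteration: `iteration`,
#'   `from`, `to`, `weight` (post-normalization), and for iterations `>= 1`
#'   the curvature `kappa` and transport cost `wasserstein` that produced
#'   the weight.
#' @export
tidy.flow_trace <- function(x, ...) {
  purrr::map_dfr(x$snapshots, function(s) {
    el <- igraph::as_edgelist(s$graph, names = TRUE)
    out <- tibble::tibble(iteration = s$iteration, from = el[, 1],
                          to = el[, 2],
                          weight = igraph::E(s$graph)$weight)
    if (!is.null(s$curvature)) {
      out$kappa <- s$curvature$kappa
      out$wasserstein <- s$curvature$wasserstein
    } else {
      out$kappa <- NA_real_
      out$wasserstein <- NA_real_
    }
    out
  })
}

#' Per-iteration summary of a flow trace
#'
#' @param x A `flow_trace` from [run_flow()].
#' @param ... Unused.
#' @return A tibble with one row per snapshot: surgery modularity, number of
#'   communities, cut threshold and size, and curvature summaries.
#' @export
glance.flow_trace <- function(x, ...) {
  purrr::map_dfr(x$snapshots, function(s) {
    k <- if (is.null(s$curvature)) NA_real_ else s$curvature$kappa
    tibble::tibble(
      iteration = s$iteration,
      modularity = s$surgery$modularity,
      n_communities = length(unique(s$surgery$partition$community)),
      threshold = s$surgery$threshold,
      n_cut_edges = s$surgery$n_cut_edges,
      mean_kappa = mean(k),
      min_kappa = if (all(is.na(k))) NA_real_ else min(k),
      frac_converged = if (is.null(s$curvature)) NA_real_
                       else mean(s$curvature$converged)
    )
  })
}

#' Plot the modularity trajectory of a flow trace
#'
#' @param object A `flow_trace`.
#' @param ... Unused.
#' @return A ggplot: surgery modularity and number of communities per
#'   iteration.
#' @export
autoplot.flow_trace <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$iteration, y = .data$modularity)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_communities),
                        color = "steelblue") +
    ggplot2::scale_size_continuous(name = "communities") +
    ggplot2::labs(x = "Ricci flow iteration", y = "surgery modularity",
                  title = paste0("Ricci flow (beta = ", object$beta, ")")) +
    ggplot2::theme_minimal()
}

#' Export a per-edge curvature table
#'
#' Writes the tidy per-iteration edge table of a flow trace (or a single
#' curvature table) as CSV with columns `u`, `v`, `weight`, `kappa`,
#' `iteration`.
#'
#' @param x A `flow_trace` or a curvature tibble from
#'   [curvature_all_edges()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curvature_csv <- function(x, path) {
  if (inherits(x, "flow_trace")) {
    tbl <- tidy(x)
  } else {
    tbl <- x
    tbl$iteration <- tbl$iteration %||% NA_integer_
  }
  out <- tibble::tibble(u = tbl$from, v = tbl$to, weight = tbl$weight,
                        kappa = tbl$kappa, iteration = tbl$iteration)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
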
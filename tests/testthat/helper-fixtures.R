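# Small graphs and independent oracles used across the suite.

make_triangle <- function() {
  as_orc_graph(igraph::make_graph(~ A - B, B - C, A - C))
}

make_two_node <- function(w = 1) {
  g <- igraph::make_graph(~ A - B)
  igraph::E(g)$weight <- w
  as_orc_graph(g)
}

# two triangles joined by a single bridge edge c-d
make_barbell <- function() {
  as_orc_graph(igraph::make_graph(~ a - b, b - c, a - c, d - e, e - f, d - f,
                                  c - d))
}

# two K4 cliques joined by a unit bridge (13 edges)
make_two_k4 <- function() {
  g <- igraph::make_graph(~ a - b, a - c, a - d, b - c, b - d, c - d,
                          e - f, e - g, e - h, f - g, f - h, g - h,
                          d - e)
  as_orc_graph(g)
}

make_star <- function(n_leaves = 4) {
  g <- igraph::make_star(n_leaves + 1, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("hub", paste0("leaf", seq_len(n_leaves)))
  as_orc_graph(g)
}

# random bipartite transport problem with metric costs (distances between
# random points in the plane, as in the application where costs are
# shortest-path distances); masses are rationals
random_metric_problem <- function(nl, nr) {
  P <- matrix(stats::runif(2 * nl), nl, 2)
  Q <- matrix(stats::runif(2 * nr), nr, 2)
  C <- as.matrix(stats::dist(rbind(P, Q)))[seq_len(nl), nl + seq_len(nr),
                                           drop = FALSE] / sqrt(2)
  C[C == 0] <- 1e-6
  a <- sample(1:9, nl, replace = TRUE); a <- a / sum(a)
  b <- sample(1:9, nr, replace = TRUE); b <- b / sum(b)
  orcflow:::new_bipartite_problem(paste0("L", seq_len(nl)),
                                  paste0("R", seq_len(nr)),
                                  unname(C), a, b)
}

# exact transportation optimum by enumerating all bases (spanning trees of
# the bipartite support); independent of the package's LP solver
brute_force_lp <- function(cost, supply, demand) {
  m <- length(supply); n <- length(demand)
  cells <- expand.grid(i = seq_len(m), j = seq_len(n))
  best <- Inf
  for (pick in utils::combn(nrow(cells), m + n - 1, simplify = FALSE)) {
    sub <- cells[pick, ]
    # leaf elimination on the bipartite tree; infeasible/cyclic -> NA
    q <- rep(NA_real_, length(pick))
    sup <- supply; dem <- demand
    active <- rep(TRUE, length(pick))
    repeat {
      if (!any(active)) break
      deg_i <- tabulate(sub$i[active], m)
      deg_j <- tabulate(sub$j[active], n)
      leaf_cell <- which(active & (deg_i[sub$i] == 1 | deg_j[sub$j] == 1))[1]
      if (is.na(leaf_cell)) break   # cycle: not a basis
      i <- sub$i[leaf_cell]; j <- sub$j[leaf_cell]
      amt <- if (deg_i[i] == 1) sup[i] else dem[j]
      q[leaf_cell] <- amt
      sup[i] <- sup[i] - amt; dem[j] <- dem[j] - amt
      active[leaf_cell] <- FALSE
    }
    if (any(active) || anyNA(q) || any(q < -1e-12)) next
    if (max(abs(sup), abs(dem)) > 1e-9) next
    val <- sum(q * cost[cbind(sub$i, sub$j)])
    best <- min(best, val)
  }
  best
}

# weighted shortest path by exhaustive enumeration of simple paths
brute_force_distance <- function(graph, from, to) {
  if (from == to) return(0)
  paths <- igraph::all_simple_paths(graph, from, to)
  if (length(paths) == 0) return(Inf)
  min(vapply(paths, function(p) {
    idx <- as.integer(p)
    sum(igraph::E(graph, path = idx)$weight)
  }, 0))
}

tmp_edgelist <- function(lines) {
  f <- withr::local_tempfile(fileext = ".edgelist",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
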
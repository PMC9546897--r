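#' Stochastic block model with planted communities
#'
#' N nodes split into K equal blocks (remainder spread over the first
#' blocks).  Within-block pairs are connected independently with probability
#' \eqn{p_{intra} = dK/N}; between-block pairs with \eqn{r \cdot p_{intra}}.
#' Small `r` means a crisper community structure.  Edges are unweighted
#' (weight 1).
#'
#' @param n Number of nodes.
#' @param k Number of communities.
#' @param d Expected within-community degree scale; \eqn{p_{intra} = dK/N}
#'   must land in (0, 1].
#' @param r Inter/intra connection probability ratio in `[0, 1]`.
#' @param seed Integer seed; the same parameters and seed reproduce the
#'   identical edge set.
#' @return A list with `graph` (igraph) and `partition` (planted labels).
#' @export
generate_sbm <- function(n, k, d, r, seed = 1) {
  p_intra <- d * k / n
  if (p_intra <= 0 || p_intra > 1) {
    stop("infeasible SBM: p_intra = d*K/N = ", signif(p_intra, 4),
         " must be in (0, 1]", call. = FALSE)
  }
  if (r < 0 || r > 1 || r * p_intra > 1) {
    stop("infeasible SBM: need r in [0, 1] with r*p_intra <= 1", call. = FALSE)
  }
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  pref <- matrix(r * p_intra, k, k)
  diag(pref) <- p_intra
  g <- withr::with_seed(seed, igraph::sample_sbm(n, pref, sizes))
  igraph::V(g)$name <- as.character(seq_len(n))
  igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  partition <- as_partition(tibble::tibble(
    node = as.character(seq_len(n)),
    community = as.character(rep(seq_len(k), sizes))))
  list(graph = as_orc_graph(g), partition = partition)
}

# mean of the discrete power law P(x) ~ x^-tau on lo..hi
powerlaw_mean <- function(lo, hi, tau) {
  x <- lo:hi
  p <- x^(-tau)
  sum(x * p) / sum(p)
}

sample_powerlaw <- function(m, lo, hi, tau) {
  x <- lo:hi
  sample(x, m, replace = TRUE, prob = x^(-tau))
}

# Random stub matching into simple edges.  Rejected pairs (self-loops,
# duplicates, and same-group pairs when `group` is given) are re-shuffled
# for further rounds rather than dropped, so realized degrees track the
# stub counts closely; only the final unmatched leftovers are discarded.
match_stubs <- function(stubs, group = NULL, rounds = 30) {
  edges <- matrix(integer(0), ncol = 2)
  seen <- character(0)
  for (round in seq_len(rounds)) {
    if (length(stubs) < 2) break
    stubs <- sample(stubs)
    if (length(stubs) %% 2 == 1) stubs <- stubs[-1]
    e <- matrix(stubs, ncol = 2, byrow = TRUE)
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    ok <- e[, 1] != e[, 2] & !key %in% seen & !duplicated(key)
    if (!is.null(group)) ok <- ok & group[e[, 1]] != group[e[, 2]]
    edges <- rbind(edges, e[ok, , drop = FALSE])
    seen <- c(seen, key[ok])
    stubs <- as.vector(t(e[!ok, , drop = FALSE]))
    if (all(ok)) break
  }
  edges
}

#' LFR benchmark with power-law degrees and community sizes
#'
#' Generates an undirected unweighted network with heterogeneous degrees
#' (power-law exponent `tau1`) and community sizes (exponent `tau2`).  Each
#' node spends a fraction `mu` of its degree on inter-community edges and
#' the rest inside its community; wiring uses stub matching with self-loops
#' and duplicates dropped, so realized degrees track the sampled sequence
#' statistically rather than exactly.
#'
#' @param n Number of nodes.
#' @param tau1 Degree exponent (> 1).
#' @param tau2 Community-size exponent.
#' @param d Target mean degree (sets the minimum degree given `tau1` and
#'   `k_max`).
#' @param mu Mixing fraction of inter-community edges per node, in `[0, 1]`.
#' @param max_communities Upper bound on the number of planted communities;
#'   draws violating it are retried.
#' @param k_max Maximum degree (default `2.5 d`).
#' @param s_min,s_max Community-size range (defaults scale with `d`).
#' @param seed Integer seed.
#' @param max_retries Bounded retries for the combinatorial feasibility
#'   steps before giving up with an error.
#' @return A list with `graph` and the planted `partition`.
#' @export
generate_lfr <- function(n, tau1 = 2, tau2 = 1, d = 20, mu = 0.1,
                         max_communities = 50, k_max = NULL, s_min = NULL,
                         s_max = NULL, seed = 1, max_retries = 100) {
  stopifnot(tau1 > 1, mu >= 0, mu <= 1, n > 10)
  k_max <- k_max %||% min(n - 1, ceiling(2.5 * d))
  withr::with_seed(seed, {
    # minimum degree matching the target mean under the sampled power law
    means <- vapply(seq_len(k_max - 1), function(lo)
      powerlaw_mean(lo, k_max, tau1), 0)
    k_min <- which.min(abs(means - d))
    if (abs(means[k_min] - d) > max(2, 0.2 * d)) {
      stop("LFR infeasible: cannot reach mean degree ", d,
           " with tau1 = ", tau1, ", k_max = ", k_max, call. = FALSE)
    }
    s_min <- s_min %||% max(ceiling((1 - mu) * k_min) + 1, ceiling(d / 2))
    s_max <- s_max %||% min(n, max(3 * d, ceiling(3 * n / max_communities)))
    if (s_min >= s_max) stop("LFR infeasible: s_min >= s_max", call. = FALSE)

    for (attempt in seq_len(max_retries)) {
      degrees <- sample_powerlaw(n, k_min, k_max, tau1)
      intra_deg <- round((1 - mu) * degrees)

      # community sizes: draw until they cover n, then absorb the remainder
      sizes <- integer(0)
      while (sum(sizes) < n) {
        sizes <- c(sizes, sample_powerlaw(1, s_min, s_max, tau2))
      }
      excess <- sum(sizes) - n
      if (sizes[length(sizes)] - excess >= s_min) {
        sizes[length(sizes)] <- sizes[length(sizes)] - excess
      } else {
        sizes <- sizes[-length(sizes)]
        deficit <- n - sum(sizes)
        # spread the leftover nodes over the largest communities
        ord <- order(sizes, decreasing = TRUE)
        add <- rep(deficit %/% length(sizes), length(sizes))
        add[seq_len(deficit %% length(sizes))] <- add[seq_len(deficit %% length(sizes))] + 1
        sizes[ord] <- sizes[ord] + add
      }
      if (length(sizes) > max_communities || any(sizes < 2)) next

      # assign nodes to communities, largest intra-degree first
      cap <- sizes
      assign <- integer(n)
      ord <- order(intra_deg, decreasing = TRUE)
      ok <- TRUE
      for (v in ord) {
        feas <- which(cap > 0 & sizes - 1 >= intra_deg[v])
        if (length(feas) == 0) { ok <- FALSE; break }
        c_pick <- feas[sample.int(length(feas), 1, prob = cap[feas])]
        assign[v] <- c_pick
        cap[c_pick] <- cap[c_pick] - 1
      }
      if (!ok) next

      edges <- matrix(integer(0), ncol = 2)
      # intra-community stub matching (collisions rewired, not dropped)
      for (c_id in seq_along(sizes)) {
        members <- which(assign == c_id)
        stubs <- rep(members, intra_deg[members])
        if (length(stubs) %% 2 == 1) stubs <- stubs[-sample.int(length(stubs), 1)]
        if (length(stubs) == 0) next
        edges <- rbind(edges, match_stubs(stubs))
      }
      # inter-community stub matching
      inter_stubs <- rep(seq_len(n), pmax(degrees - intra_deg, 0))
      if (length(inter_stubs) %% 2 == 1) {
        inter_stubs <- inter_stubs[-sample.int(length(inter_stubs), 1)]
      }
      if (length(inter_stubs) > 0) {
        edges <- rbind(edges, match_stubs(inter_stubs, group = assign))
      }

      g <- igraph::graph_from_edgelist(
        matrix(as.character(edges), ncol = 2), directed = FALSE)
      missing <- setdiff(as.character(seq_len(n)), igraph::V(g)$name)
      if (length(missing) > 0) g <- igraph::add_vertices(g, length(missing),
                                                         name = missing)
      igraph::E(g)$weight <- rep(1, igraph::ecount(g))
      g <- as_orc_graph(g)
      partition <- as_partition(tibble::tibble(
        node = as.character(seq_len(n)),
        community = as.character(assign)))
      return(list(graph = g, partition = partition))
    }
    stop("LFR generator failed after ", max_retries,
         " attempts: constraints unsatisfiable", call. = FALSE)
  })
}

#' Flip adjacency-matrix entries at random
#'
#' Semi-synthetic noise test: toggles the existence of `R = round(r |V|^2)`
#' distinct unordered node pairs chosen uniformly at random (symmetric
#' flips; created edges get weight 1).  `mode = "bernoulli"` instead flips
#' each pair independently with probability `p`.
#'
#' @param graph An igraph object.
#' @param r Flip intensity; `R = round(r * n^2)` pairs are toggled.
#' @param seed Integer seed.
#' @param mode `"count"` (default, the R-pairs rule) or `"bernoulli"`.
#' @param p Per-pair flip probability for `mode = "bernoulli"`.
#' @return The perturbed graph.
#' @export
flip_entries <- function(graph, r, seed = 1, mode = c("count", "bernoulli"),
                         p = 0.1) {
  mode <- match.arg(mode)
  graph <- as_orc_graph(graph)
  n <- igraph::vcount(graph)
  nm <- igraph::V(graph)$name
  n_pairs <- n * (n - 1) / 2
  pairs_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  withr::with_seed(seed, {
    if (mode == "count") {
      R <- round(r * n^2)
      if (R > n_pairs) {
        stop("R = ", R, " exceeds the ", n_pairs, " available node pairs",
             call. = FALSE)
      }
      sel <- if (R > 0) sample.int(n_pairs, R) else integer(0)
    } else {
      sel <- which(stats::runif(n_pairs) < p)
    }
  })
  if (length(sel) == 0) return(graph)
  u <- nm[pairs_idx[sel, 1]]
  v <- nm[pairs_idx[sel, 2]]
  adj <- igraph::as_adjacency_matrix(graph, sparse = TRUE) > 0
  existing <- adj[cbind(pairs_idx[sel, 1], pairs_idx[sel, 2])]
  g <- igraph::delete_edges(
    graph, igraph::get_edge_ids(graph, rbind(u[existing], v[existing])))
  if (any(!existing)) {
    g <- igraph::add_edges(g, rbind(u[!existing], v[!existing]),
                           weight = 1)
  }
  as_orc_graph(g)
}

#' Remove within-community edges at random
#'
#' Semi-synthetic structure-weakening test: removes `R = round(r |E|)`
#' intra-community edges (under the ground-truth partition) uniformly at
#' random, one at a time.  Only edges whose endpoints both currently have
#' degree at least 2 are eligible, re-evaluated after every removal, so the
#' perturbation never creates an isolated node or touches a leaf.
#'
#' @param graph An igraph object.
#' @param truth Ground-truth partition.
#' @param r Removal intensity; `R = round(r * |E|)` edges are removed.
#' @param seed Integer seed.
#' @return The perturbed graph.
#' @export
remove_intra_edges <- function(graph, truth, r, seed = 1) {
  graph <- as_orc_graph(graph)
  truth <- as_partition(truth)
  R <- round(r * igraph::ecount(graph))
  withr::with_seed(seed, {
    for (step in seq_len(R)) {
      el <- igraph::as_edgelist(graph, names = TRUE)
      comm <- stats::setNames(truth$community, truth$node)
      deg <- igraph::degree(graph)
      eligible <- which(comm[el[, 1]] == comm[el[, 2]] &
                          deg[el[, 1]] >= 2 & deg[el[, 2]] >= 2)
      if (length(eligible) == 0) {
        stop("eligible intra-community edges exhausted after ", step - 1,
             " of ", R, " removals", call. = FALSE)
      }
      graph <- igraph::delete_edges(graph, eligible[sample.int(length(eligible), 1)])
    }
  })
  graph
}

#' Benchmark sweep over synthetic networks
#'
#' For every generator parameter value and seed, generates a network with
#' planted communities, runs [detect_communities()] for each `beta`
#' (selection by ARI against the planted labels, the benchmarking
#' protocol), and records the recovery score.
#'
#' @param generator `"sbm"` (parameter = inter/intra ratio `r`) or `"lfr"`
#'   (parameter = mixing `mu`).
#' @param params Numeric vector of generator parameter values to sweep.
#' @param betas Traffic rates to compare.
#' @param n_seeds Network realisations per parameter value.
#' @param max_iter Ricci flow iterations per run.
#' @param n,k,d Generator size parameters (`k` is ignored for LFR).
#' @param seed Base seed; realisation seeds are derived from it.
#' @param solver Transport solver passed to [detect_communities()].
#' @param ... Further arguments to [generate_lfr()].
#' @return A tibble with columns `generator`, `param`, `beta`, `seed`,
#'   `ari`, `n_communities`, `iteration`.  Failed runs are recorded as `NA`
#'   with a warning.
#' @export
run_benchmark <- function(generator = c("sbm", "lfr"), params, betas = 1,
                          n_seeds = 10, max_iter = 15, n = 500, k = 3,
                          d = 15, seed = 1, solver = "dmk", ...) {
  generator <- match.arg(generator)
  grid <- tidyr::expand_grid(param = params, realisation = seq_len(n_seeds),
                             beta = betas)
  rows <- purrr::pmap(grid, function(param, realisation, beta) {
    gseed <- (seed * 1000L + match(param, params) * 100L + realisation) %% .Machine$integer.max
    out <- tryCatch({
      net <- if (generator == "sbm") {
        generate_sbm(n, k, d, r = param, seed = gseed)
      } else {
        generate_lfr(n, d = d, mu = param, seed = gseed, ...)
      }
      fit <- suppressWarnings(detect_communities(
        net$graph, beta = beta, max_iter = max_iter, selection = "ari",
        truth = net$partition, solver = solver))
      tibble::tibble(ari = fit$score,
                     n_communities = length(unique(fit$partition$community)),
                     iteration = fit$iteration)
    }, error = function(e) {
      warning("benchmark run failed (param = ", param, ", seed = ", gseed,
              "): ", conditionMessage(e), call. = FALSE)
      tibble::tibble(ari = NA_real_, n_communities = NA_integer_,
                     iteration = NA_integer_)
    })
    dplyr::bind_cols(tibble::tibble(generator = generator, param = param,
                                    beta = beta, seed = gseed), out)
  })
  dplyr::bind_rows(rows)
}

#' Summarize a benchmark sweep
#'
#' @param results Output of [run_benchmark()].
#' @return Mean and standard deviation of the ARI per parameter value and
#'   beta.
#' @export
summarize_benchmark <- function(results) {
  dplyr::summarise(
    dplyr::group_by(results, .data$generator, .data$param, .data$beta),
    mean_ari = mean(.data$ari, na.rm = TRUE),
    sd_ari = stats::sd(.data$ari, na.rm = TRUE),
    n = dplyr::n(), .groups = "drop")
}

#' Plot a benchmark sweep
#'
#' @param results Output of [run_benchmark()].
#' @return A ggplot of mean ARI (ribbon = one standard deviation) against
#'   the generator parameter, one line per beta.
#' @export
plot_benchmark <- function(results) {
  s <- summarize_benchmark(results)
  s$beta <- factor(s$beta)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$param, y = .data$mean_ari,
                                  color = .data$beta, fill = .data$beta)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_ari - .data$sd_ari,
                                      ymax = .data$mean_ari + .data$sd_ari),
                         alpha = 0.15, color = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "generator parameter", y = "mean ARI") +
    ggplot2::theme_minimal()
}

#' Pairwise win rate between two methods
#'
#' Fraction of paired instances on which method A scores at least as high
#' as method B.  The tie policy is explicit: `"first"` (default) counts
#' ties as wins for A, `"half"` splits them, `"none"` ignores them.
#'
#' @param ari_a,ari_b Equal-length numeric vectors of per-instance scores.
#' @param ties Tie-handling policy.
#' @return A fraction in `[0, 1]`.
#' @export
pairwise_win_rate <- function(ari_a, ari_b, ties = c("first", "half", "none")) {
  ties <- match.arg(ties)
  if (length(ari_a) != length(ari_b)) {
    stop("paired score lists must have equal length", call. = FALSE)
  }
  switch(ties,
         first = mean(ari_a >= ari_b),
         half = mean(ari_a > ari_b) + 0.5 * mean(ari_a == ari_b),
         none = mean(ari_a > ari_b))
}

#' Compare methods on perturbed versions of a real network
#'
#' Reproduces the semi-synthetic robustness protocol: for each perturbation
#' intensity `r`, generates `n_instances` perturbed copies of `graph`
#' (intra-community edge removal or adjacency flips), then scores three
#' detectors against the ground truth on each instance: the curvature flow
#' at its best `beta`, the Sinkhorn-based flow baseline, and Infomap.
#'
#' @param graph An igraph object with ground truth `truth`.
#' @param truth Ground-truth partition.
#' @param r_values Perturbation intensities.
#' @param n_instances Perturbed copies per intensity.
#' @param mode `"remove_intra"` or `"flip"`.
#' @param betas Traffic rates over which the flow's best result is taken.
#' @param max_iter Ricci flow iterations.
#' @param seed Base seed.
#' @return A tibble with columns `r`, `instance`, `method`, `ari`.
#' @export
compare_on_perturbations <- function(graph, truth, r_values = c(0.01, 0.03, 0.05, 0.07),
                                     n_instances = 20,
                                     mode = c("remove_intra", "flip"),
                                     betas = c(0.1, 0.5, 1, 1.5, 2),
                                     max_iter = 15, seed = 1) {
  mode <- match.arg(mode)
  graph <- as_orc_graph(graph)
  truth <- as_partition(truth)
  grid <- tidyr::expand_grid(r = r_values, instance = seq_len(n_instances))
  rows <- purrr::pmap(grid, function(r, instance) {
    pseed <- (seed * 7919L + round(r * 10000L) + instance) %% .Machine$integer.max
    pg <- if (mode == "remove_intra") {
      remove_intra_edges(graph, truth, r, seed = pseed)
    } else {
      flip_entries(graph, r, seed = pseed)
    }
    orc <- max(vapply(betas, function(b) {
      suppressWarnings(detect_communities(pg, beta = b, max_iter = max_iter,
                                          selection = "ari",
                                          truth = truth)$score)
    }, 0))
    sink_fit <- suppressWarnings(detect_communities(
      pg, max_iter = max_iter, selection = "ari", truth = truth,
      solver = "sinkhorn"))
    im <- withr::with_seed(pseed, igraph::cluster_infomap(pg))
    im_part <- as_partition(stats::setNames(
      as.character(igraph::membership(im)), igraph::V(pg)$name))
    tibble::tibble(r = r, instance = instance,
                   method = c("orc", "sinkhorn", "infomap"),
                   ari = c(orc, sink_fit$score,
                           adjusted_rand_index(im_part, truth)))
  })
  dplyr::bind_rows(rows)
}
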
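test_that("SBM generation follows the planted-partition parameterization", {
  expect_error(generate_sbm(10, 3, 15, 0.1), "p_intra")   # d*K/N > 1
  expect_error(generate_sbm(500, 3, 15, 1.5), "r in")

  net <- generate_sbm(90, 3, 10, r = 0, seed = 4)
  comm <- stats::setNames(net$partition$community, net$partition$node)
  el <- igraph::as_edgelist(net$graph)
  expect_equal(sum(comm[el[, 1]] != comm[el[, 2]]), 0)   # r = 0: no inter

  expect_equal(length(unique(net$partition$community)), 3)
  expect_lte(diff(range(table(net$partition$community))), 1)

  # determinism: same seed, identical edge set
  a <- generate_sbm(60, 3, 8, 0.1, seed = 9)
  b <- generate_sbm(60, 3, 8, 0.1, seed = 9)
  expect_identical(igraph::as_edgelist(a$graph), igraph::as_edgelist(b$graph))
  c <- generate_sbm(60, 3, 8, 0.1, seed = 10)
  expect_false(identical(igraph::as_edgelist(a$graph),
                         igraph::as_edgelist(c$graph)))
})

test_that("SBM mean degree matches its Monte-Carlo expectation", {
  n <- 600; k <- 3; d <- 15; r <- 0.1
  p_intra <- d * k / n
  nb <- n / k
  expected <- p_intra * (nb - 1) + r * p_intra * (n - nb)
  degs <- vapply(1:20, function(s) {
    mean(igraph::degree(generate_sbm(n, k, d, r, seed = s)$graph))
  }, 0)
  se <- stats::sd(degs) / sqrt(length(degs))
  expect_lt(abs(mean(degs) - expected), 3 * se + 0.05)
})

test_that("LFR produces power-law structure with the requested mixing", {
  l0 <- generate_lfr(300, d = 12, mu = 0, seed = 2)
  comm <- stats::setNames(l0$partition$community, l0$partition$node)
  el <- igraph::as_edgelist(l0$graph)
  expect_equal(sum(comm[el[, 1]] != comm[el[, 2]]), 0)

  # community count near the planted range at the benchmark parameters
  l <- generate_lfr(500, tau1 = 2, tau2 = 1, d = 20, mu = 0.35, seed = 5)
  K <- length(unique(l$partition$community))
  expect_gte(K, 12); expect_lte(K, 30)
  el <- igraph::as_edgelist(l$graph)
  comm <- stats::setNames(l$partition$community, l$partition$node)
  mu_hat <- mean(comm[el[, 1]] != comm[el[, 2]])
  expect_lt(abs(mu_hat - 0.35), 0.1)

  # degree-distribution tail exponent ~ tau1 (discrete Hill/MLE estimate)
  lt <- generate_lfr(1500, tau1 = 2, d = 20, mu = 0.2, seed = 3)
  kk <- igraph::degree(lt$graph)
  ks <- kk[kk >= 8]
  alpha_hat <- 1 + length(ks) / sum(log(ks / 7.5))
  expect_gt(alpha_hat, 1.5); expect_lt(alpha_hat, 2.7)

  # determinism
  a <- generate_lfr(200, d = 10, mu = 0.2, seed = 7)
  b <- generate_lfr(200, d = 10, mu = 0.2, seed = 7)
  expect_identical(igraph::as_edgelist(a$graph), igraph::as_edgelist(b$graph))
  expect_identical(a$partition, b$partition)
})

test_that("adjacency flipping toggles exactly the sampled pairs", {
  net <- generate_sbm(60, 3, 10, 0.05, seed = 1)
  g <- net$graph
  expect_identical(igraph::as_edgelist(flip_entries(g, 0, seed = 5)),
                   igraph::as_edgelist(g))

  nm <- sort(igraph::V(g)$name)
  A1 <- igraph::as_adjacency_matrix(g, sparse = FALSE)[nm, nm] > 0
  pf <- flip_entries(g, 0.01, seed = 2)
  A2 <- igraph::as_adjacency_matrix(pf, sparse = FALSE)[nm, nm] > 0
  expect_equal(sum(A1 != A2) / 2, round(0.01 * 60^2))

  # flipping the same pairs again restores the original graph
  back <- flip_entries(pf, 0.01, seed = 2)
  A3 <- igraph::as_adjacency_matrix(back, sparse = FALSE)[nm, nm] > 0
  expect_identical(A3, A1)

  # a complete graph with every pair flipped empties out
  k5 <- as_orc_graph(igraph::make_full_graph(5))
  flipped <- flip_entries(k5, r = 10 / 25, seed = 1)
  expect_equal(igraph::ecount(flipped), 0)

  expect_error(flip_entries(k5, r = 1, seed = 1), "exceeds")
})

test_that("intra-community removal respects eligibility and leaves no leaves behind", {
  net <- generate_sbm(60, 3, 10, 0.05, seed = 1)
  expect_identical(
    igraph::as_edgelist(remove_intra_edges(net$graph, net$partition, 0,
                                           seed = 3)),
    igraph::as_edgelist(net$graph))

  m0 <- igraph::ecount(net$graph)
  pr <- remove_intra_edges(net$graph, net$partition, 0.1, seed = 3)
  expect_equal(igraph::ecount(pr), m0 - round(0.1 * m0))
  expect_gte(min(igraph::degree(pr)), 1)

  # every removed edge was intra-community under the truth
  comm <- stats::setNames(net$partition$community, net$partition$node)
  key <- function(el) paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  removed <- setdiff(key(igraph::as_edgelist(net$graph)),
                     key(igraph::as_edgelist(pr)))
  u <- sub(" .*", "", removed); v <- sub(".* ", "", removed)
  expect_true(all(comm[u] == comm[v]))

  # exhaustion errors with the achieved count reported
  path <- read_graph_file(tmp_edgelist(c("1 2", "2 3", "3 4")))
  truth <- as_partition(stats::setNames(rep("a", 4), as.character(1:4)))
  expect_error(remove_intra_edges(path, truth, r = 1, seed = 1), "exhausted")
})

test_that("benchmark sweeps tabulate per-run recovery", {
  res <- run_benchmark("sbm", params = 0.02, betas = c(1, 2), n_seeds = 1,
                       n = 40, k = 2, d = 8, max_iter = 5, seed = 1)
  expect_equal(nrow(res), 2)
  expect_named(res, c("generator", "param", "beta", "seed", "ari",
                      "n_communities", "iteration"))
  expect_true(all(res$ari >= -0.5 & res$ari <= 1))

  s <- summarize_benchmark(res)
  expect_equal(nrow(s), 2)
  expect_true(all(c("mean_ari", "sd_ari") %in% names(s)))
})

test_that("pairwise win rates count ties by the documented policy", {
  expect_equal(pairwise_win_rate(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(pairwise_win_rate(c(0, 0), c(0.5, 1)), 0)
  expect_error(pairwise_win_rate(1:3 / 3, 1:2 / 2), "equal length")

  withr::with_seed(61, {
    a <- stats::runif(50); b <- stats::runif(50)
    expect_equal(pairwise_win_rate(a, b), sum(a >= b) / 50)
    expect_equal(pairwise_win_rate(a, b, ties = "half"),
                 (sum(a > b) + 0.5 * sum(a == b)) / 50)
    expect_equal(pairwise_win_rate(a, b, ties = "none"), mean(a > b))
  })
})
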
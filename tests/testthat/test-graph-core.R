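test_that("edge lists parse with default weights, collapsing and validation", {
  g <- read_graph_file(tmp_edgelist(c("1 2", "2 3")))
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::E(g)$weight, c(1, 1))

  # duplicate rows collapse to one edge, keeping the first weight
  g2 <- read_graph_file(tmp_edgelist(c("1 2 0.7", "1 2 0.9", "2 3")))
  expect_equal(igraph::ecount(g2), 2)
  w12 <- igraph::E(g2)$weight[igraph::get_edge_ids(g2, c("1", "2"))]
  expect_equal(w12, 0.7)

  # self-loops dropped; comma separation accepted
  g3 <- read_graph_file(tmp_edgelist(c("a,a,2", "a,b,3")))
  expect_equal(igraph::ecount(g3), 1)

  expect_error(read_graph_file(tmp_edgelist(c("1 2", "badline_only"))),
               "line 2")
  expect_error(read_graph_file(tmp_edgelist(c("1 2 notanumber"))),
               "non-numeric")
  expect_error(read_graph_file(tmp_edgelist(c("# only a comment"))), "empty")
  expect_error(read_graph_file("/nonexistent/file.edgelist"), "not found")
})

test_that("GML round trip preserves nodes, edges and weights", {
  g <- make_two_k4()
  igraph::E(g)$weight <- seq(0.1, 1.3, by = 0.1)
  f <- withr::local_tempfile(fileext = ".gml")
  write_graph_file(g, f)
  g2 <- read_graph_file(f)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  ids <- igraph::get_edge_ids(g2, t(igraph::as_edgelist(g)))
  expect_equal(igraph::E(g2)$weight[ids], igraph::E(g)$weight)

  f2 <- withr::local_tempfile(fileext = ".edgelist")
  write_graph_file(g, f2)
  g3 <- read_graph_file(f2)
  expect_equal(igraph::ecount(g3), 13)
  ids <- igraph::get_edge_ids(g3, t(igraph::as_edgelist(g)))
  expect_equal(igraph::E(g3)$weight[ids], igraph::E(g)$weight)
})

test_that("shortest-path distances match exhaustive path enumeration", {
  path <- read_graph_file(tmp_edgelist(c("1 2", "2 3")))
  expect_equal(shortest_path_distance(path, "1", "3"), 2)
  expect_equal(shortest_path_distance(make_two_node(0.4), "A", "B"), 0.4)

  withr::with_seed(11, {
    for (rep in 1:8) {
      g <- igraph::sample_gnp(7, 0.5)
      igraph::V(g)$name <- as.character(1:7)
      if (igraph::ecount(g) == 0) next
      igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.1, 1)
      g <- as_orc_graph(g)
      D <- shortest_path_distance(g)
      expect_equal(D, t(D))
      for (i in c("1", "4")) for (j in c("3", "7")) {
        expect_equal(D[i, j], brute_force_distance(g, i, j), tolerance = 1e-12)
      }
      # triangle inequality through every intermediate node
      n <- igraph::vcount(g)
      for (k in seq_len(n)) {
        expect_true(all(D <= outer(D[, k], D[k, ], `+`) + 1e-12))
      }
    }
  })
})

test_that("modularity matches hand-evaluated worked cases", {
  g <- make_two_k4()
  blocks <- as_partition(c(a = "1", b = "1", c = "1", d = "1",
                           e = "2", f = "2", g = "2", h = "2"))
  expect_equal(graph_modularity(g, blocks), 12 / 13 - 1 / 2, tolerance = 1e-12)

  one <- as_partition(stats::setNames(rep("x", 8), igraph::V(g)$name))
  expect_equal(graph_modularity(g, one), 0)

  singles <- as_partition(stats::setNames(igraph::V(g)$name,
                                          igraph::V(g)$name))
  deg <- igraph::degree(g)
  expect_equal(graph_modularity(g, singles), -sum((deg / (2 * 13))^2))

  expect_error(graph_modularity(g, as_partition(c(a = "1"))), "missing")
})

test_that("weight normalization rescales to unit total and is idempotent", {
  gn <- normalize_weights(read_graph_file(tmp_edgelist(c("1 2 2", "2 3 2"))))
  expect_equal(sort(igraph::E(gn)$weight), c(0.5, 0.5))

  g13 <- read_graph_file(tmp_edgelist(c("1 2 1", "2 3 3")))
  expect_equal(sort(igraph::E(normalize_weights(g13))$weight), c(0.25, 0.75))
  expect_equal(igraph::E(normalize_weights(make_two_node(7)))$weight, 1)

  twice <- normalize_weights(normalize_weights(g13))
  expect_equal(igraph::E(twice)$weight,
               igraph::E(normalize_weights(g13))$weight, tolerance = 1e-12)
})

test_that("graph statistics match closed forms on regular graphs", {
  s <- graph_stats(make_triangle())
  expect_equal(s$avg_degree, 2)
  expect_equal(s$avg_clustering, 1)
  expect_equal(s$n_edges, 3)

  star <- graph_stats(make_star(4))
  expect_equal(star$avg_clustering, 0)
  expect_equal(star$avg_degree, 2 * 4 / 5)
})
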